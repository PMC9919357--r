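test_that("resonance width round-trips between rad/s and Hz exactly", {
  r <- resonance(77.5, 2.3, 573)
  expect_identical(width_hz(r), 573)
  expect_identical(r$a, pi * 573)
  expect_error(resonance(77.5, -0.1, 573), "amplitude")
  expect_error(resonance(77.5, 2.3, 0), "width")
})

test_that("model parameter sets enforce ordering and distinct positions", {
  p <- zspec_params(1, list(resonance(60, 0.1, 100), resonance(90, 0.2, 200)))
  expect_equal(vapply(p$resonances, `[[`, numeric(1), "b"), c(90, 60))
  expect_error(
    zspec_params(1, list(resonance(60, 0.1, 100), resonance(60, 0.2, 200))),
    "degenerate")
  expect_error(zspec_params(0, list()), "baseline")
})

test_that("empty product gives the flat baseline and on-resonance dip is exp(-B)", {
  acq <- acq_default
  expect_equal(evaluate_zspectrum(zspec_params(2.5, list()), c(10, 50, 200), acq),
               rep(2.5, 3))
  p <- zspec_params(1.3, list(resonance(80, 1.7, 400)))
  expect_equal(evaluate_zspectrum(p, 80, acq), 1.3 * exp(-1.7))
})

test_that("product model matches independent per-term arithmetic on the apo set", {
  acq <- acq_default
  for (x in c(77.5, 60.1, 103.3, 196)) {
    expect_equal(evaluate_zspectrum(apo_params, x, acq),
                 oracle_zvalue(apo_params, x, acq), tolerance = 1e-12)
  }
})

test_that("spectrum stays within (0, A] and recovers A far off resonance", {
  acq <- acq_default
  grid <- acq_grid_ppm(acq)
  s <- evaluate_zspectrum(apo_params, grid, acq)
  expect_true(all(s > 0 & s <= apo_params$A))
  # 1e4 half-widths from every resonance
  wmax <- max(vapply(apo_params$resonances, width_hz, numeric(1)))
  far <- 77.5 + hz_to_ppm(1e4 * wmax, acq)
  expect_lt(abs(evaluate_zspectrum(apo_params, far, acq) - apo_params$A) /
              apo_params$A, 1e-6)
})

test_that("evaluation is invariant under permutation of the resonance list", {
  acq <- acq_default
  grid <- acq_grid_ppm(acq)
  res <- apo_params$resonances
  set.seed(42)
  for (i in 1:5) {
    p2 <- zspec_params(apo_params$A, sample(res))
    expect_equal(evaluate_zspectrum(p2, grid, acq),
                 evaluate_zspectrum(apo_params, grid, acq))
  }
})

test_that("linearized evaluator is exact for a lone strong resonance and flat for B = 0", {
  acq <- acq_default
  grid <- acq_grid_ppm(acq)
  one <- zspec_params(1, list(resonance(77.5, 2.3, 573)))
  expect_equal(evaluate_zspectrum_linearized(one, grid, acq),
               evaluate_zspectrum(one, grid, acq))
  # all-zero amplitudes: flat baseline (B = 0 is allowed, widths arbitrary)
  flat <- zspec_params(1, list(resonance(80, 0, 300), resonance(60, 0, 300)))
  expect_equal(evaluate_zspectrum_linearized(flat, grid, acq),
               rep(1, length(grid)))
})

test_that("linearized error obeys the Taylor bound and shrinks quadratically", {
  acq <- acq_default
  grid <- acq_grid_ppm(acq)
  dev_at_scale <- function(scale) {
    res <- lapply(apo_params$resonances, function(r) {
      if (r$B > 1) r else resonance(r$b, r$B * scale, width_hz(r))
    })
    p <- zspec_params(1, res)
    max(abs(evaluate_zspectrum_linearized(p, grid, acq) -
              evaluate_zspectrum(p, grid, acq))) / p$A
  }
  b_weak_max <- max(vapply(apo_params$resonances, function(r)
    if (r$B > 1) 0 else r$B, numeric(1)))
  expect_lt(dev_at_scale(1), 2 * b_weak_max^2)
  d1 <- dev_at_scale(1); d2 <- dev_at_scale(1 / 2); d4 <- dev_at_scale(1 / 4)
  # quadratic shrinkage: halving amplitudes cuts the error by ~4
  expect_lt(d2 / d1, 0.3)
  expect_lt(d4 / d2, 0.3)
})

test_that("linearization warns when a non-dominant amplitude reaches 1", {
  p <- zspec_params(1, list(resonance(80, 2.5, 500), resonance(60, 1.2, 300)))
  expect_warning(evaluate_zspectrum_linearized(p, 70, acq_default),
                 "accuracy loss")
})

test_that("cest_amplitude follows the closed form and its limits", {
  acq <- acquisition_params(omega1 = 2 * pi * 99, t_sat = 20)
  expect_equal(cest_amplitude(exchange_params(1, 320, 0),
                              acquisition_params(omega1 = 0)), 0)
  expect_equal(cest_amplitude(exchange_params(0, 320, 50), acq), 0)
  # independent scalar arithmetic of the closed form
  w2 <- (2 * pi * 99)^2
  expect_equal(cest_amplitude(exchange_params(1, 320, 0), acq),
               20 * 1 * w2 / (w2 + 320^2))
  # linear in t_sat and k_on
  b1 <- cest_amplitude(exchange_params(2, 100, 30), acq)
  acq2 <- acquisition_params(omega1 = 2 * pi * 99, t_sat = 40)
  expect_equal(cest_amplitude(exchange_params(2, 100, 30), acq2), 2 * b1)
  expect_equal(cest_amplitude(exchange_params(4, 100, 30), acq), 2 * b1)
  expect_error(cest_amplitude(exchange_params(1, 0, 0),
                              acquisition_params(omega1 = 0)), "degenerate")
})

test_that("cest_width reduces to omega1 without exchange and relaxation", {
  acq <- acquisition_params(omega1 = 2 * pi * 99)
  expect_equal(cest_width(exchange_params(1, 0, 0), acq), 2 * pi * 99)
  expect_error(cest_width(exchange_params(0, 0, 0),
                          acquisition_params(omega1 = 0)), "zero")
  expect_error(cest_width(exchange_params(1, 0, 100), acq), "unbounded")
})

test_that("cest_width never decreases in R2 or omega1 over a parameter lattice", {
  acq <- function(w1) acquisition_params(omega1 = w1)
  for (koff in c(5, 50, 320)) {
    for (w1 in c(100, 622, 2000)) {
      a_prev <- -Inf
      for (R2 in c(0, 10, 100, 1000, 2000)) {
        a <- cest_width(exchange_params(1, koff, R2), acq(w1))
        expect_gte(a, a_prev)
        a_prev <- a
      }
    }
    for (R2 in c(0, 100, 1000)) {
      a_prev <- -Inf
      for (w1 in c(50, 100, 622, 1000, 3000)) {
        a <- cest_width(exchange_params(1, koff, R2), acq(w1))
        expect_gte(a, a_prev)
        a_prev <- a
      }
    }
  }
})

test_that("high-power width limit agrees with the full form when R2 >> k_off", {
  acq <- acquisition_params(omega1 = 2 * pi * 99)
  ex <- exchange_params(1, 10, 2000)
  full <- cest_width(ex, acq)
  simp <- width_high_power_limit(ex, acq)
  expect_lt(abs(full - simp) / full, 0.01)
  expect_equal(width_high_power_limit(exchange_params(1, 0, 0), acq),
               2 * pi * 99)
  expect_warning(width_high_power_limit(exchange_params(1, 320, 100), acq),
                 "comparable")
})

test_that("ppm/Hz conversion is exact and invertible", {
  acq <- acquisition_params(f_obs = 83.0e6)
  expect_equal(ppm_to_hz(0, acq), 0)
  expect_equal(ppm_to_hz(1, acq), 83.0)
  x <- c(-156.3, 0.02, 77.5, 256)
  expect_equal(hz_to_ppm(ppm_to_hz(x, acq), acq), x)
})

test_that("off-rates from line widths follow the selected convention", {
  expect_equal(koff_from_linewidth(320), 320)
  expect_equal(koff_from_linewidth(24, "numeric"), 24)
  expect_equal(koff_from_linewidth(320, "lorentzian"), pi * 320)
  expect_error(koff_from_linewidth(320, "fwhm"))
  expect_error(koff_from_linewidth(-1), "fwhm_hz")
})

test_that("acquisition grid reproduces the 91-point saturation series", {
  g <- acq_grid_ppm(acq_default)
  expect_length(g, 91)
  expect_equal(max(g), 196 + 5000 / 83)
  expect_equal(min(g), 196 - 13000 / 83)
  expect_equal(diff(g)[1], 200 / 83)
})
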