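# Default box constraints for the fit, chosen to span typical cryptophane
# hyperCEST parameters with wide margins: amplitudes 0..10, widths (a/pi)
# 10..5000 Hz, positions inside the sampled band +/- 2 ppm.
.default_bounds <- function(z) {
  band <- range(z$offsets)
  list(A = c(1e-8, Inf),
       b = c(band[1] - 2, band[2] + 2),
       B = c(0, 10),
       w = c(10, 5000))
}

# pack/unpack between an xe_zspec_params and the flat parameter vector
# c(A, b_1..b_n, B_1..B_n, w_1..w_n) used by the optimizer (w = a/pi in Hz)
.pack <- function(params) {
  df <- as.data.frame(params)
  c(A = params$A, b = df$b_ppm, B = df$B, w = df$width_hz)
}
.unpack <- function(p, n) {
  b <- p[1 + seq_len(n)]
  # optimizer iterates are allowed to collide; only the returned object
  # must satisfy the distinct-position invariant
  while (anyDuplicated(b)) {
    j <- which(duplicated(b))[1]
    b[j] <- b[j] + 1e-9
  }
  res <- lapply(seq_len(n), function(i)
    resonance(unname(b[i]), max(unname(p[1 + n + i]), 0),
              max(unname(p[1 + 2 * n + i]), 1e-6)))
  zspec_params(unname(p[1]), res)
}

# validation-free model evaluation on the flat parameter vector, used
# inside the optimizer loop
.eval_raw <- function(p, n, offsets, acq) {
  b <- p[1 + seq_len(n)]
  B <- p[1 + n + seq_len(n)]
  a <- pi * p[1 + 2 * n + seq_len(n)]
  d <- 2 * pi * ppm_to_hz(outer(offsets, b, function(x, bb) bb - x), acq)
  p[1] * exp(-drop((1 / (1 + sweep(d^2, 2, a^2, "/"))) %*% B))
}

# Estimate one Lorentzian component of an absorption trace: peak position
# (parabolic sub-grid refinement), height, and width from the interpolated
# half-height span. At half height the full span in Hz equals a/pi exactly.
.absorption_component <- function(tr, x, acq, win = NULL) {
  trw <- tr
  if (!is.null(win)) trw[!win] <- -Inf
  i0 <- which.max(trw)
  h <- tr[i0]
  m <- length(tr)
  b <- x[i0]
  if (i0 > 1L && i0 < m) {
    y1 <- tr[i0 - 1]; y2 <- tr[i0]; y3 <- tr[i0 + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      dlt <- 0.5 * (y1 - y3) / den
      if (abs(dlt) < 1) {
        b <- x[i0] + dlt * (x[i0 + 1] - x[i0])
        h <- y2 - 0.25 * (y1 - y3) * dlt
      }
    }
  }
  half <- h / 2
  xl <- x[1]
  if (i0 > 1L) for (l in seq(i0, 2L)) if (tr[l - 1] <= half) {
    f <- (tr[l] - half) / (tr[l] - tr[l - 1])
    xl <- x[l] + f * (x[l - 1] - x[l]); break
  }
  xr <- x[m]
  if (i0 < m) for (r in seq(i0, m - 1L)) if (tr[r + 1] <= half) {
    f <- (tr[r] - half) / (tr[r] - tr[r + 1])
    xr <- x[r] + f * (x[r + 1] - x[r]); break
  }
  w <- max(min(ppm_to_hz(abs(xr - xl), acq), 5000), 10)
  list(b = b, h = max(h, 0.01), w = w)
}

#' Initial parameter guess for an n-resonance fit
#'
#' Works on the effective absorption \code{t(x) = -log(S(x)/A)}, under
#' which the product model becomes a plain sum of Lorentzian components.
#' The baseline \code{A} is initialized to the upper-quantile intensity.
#' Components are then extracted greedily: the deepest remaining feature
#' of the (lightly smoothed) absorption supplies a position, its height
#' the amplitude \code{B}, and its half-height span the width; the implied
#' Lorentzian is subtracted and the search repeats. This resolves shoulder
#' resonances that never form their own local minimum of the spectrum.
#' When the residual absorption carries no feature above the noise floor,
#' remaining positions are spread evenly across the sampled band, with a
#' warning, unless \code{fallback = FALSE}.
#'
#' @param z an \code{xe_zspectrum}.
#' @param n number of resonances (>= 1); the spectrum must have at least
#'   \code{4n + 1} points.
#' @param acq an \code{xe_acq} (ppm/Hz conversion).
#' @param fallback allow equal-spacing placement when too few features are
#'   found.
#' @return an \code{xe_zspec_params}.
#' @export
initial_guess <- function(z, n, acq = acquisition_params(), fallback = TRUE) {
  stopifnot(inherits(z, "xe_zspectrum"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (length(z$offsets) < 4L * n + 1L)
    stop("too few points for an ", n, "-resonance guess")
  x <- z$offsets
  y <- z$intensities
  A0 <- stats::quantile(y, 0.9, names = FALSE)
  # effective absorption: the product model is a sum of Lorentzians here
  tr <- -log(pmax(pmin(y / A0, 1), 1e-10))
  # noise floor from twice-differenced intensities (smooth trends cancel)
  sigma_hat <- stats::mad(diff(y, differences = 2)) / sqrt(6)
  noise_floor <- max(4 * sigma_hat, 1e-4)
  if (sigma_hat > 1e-4 * A0) {
    # visible point noise: smooth the absorption before feature extraction
    trs <- as.numeric(stats::filter(tr, rep(1 / 5, 5), sides = 2))
    trs[is.na(trs)] <- tr[is.na(trs)]
    tr <- trs
  }

  lor <- function(b, w, xx) {
    a <- pi * w
    d <- 2 * pi * ppm_to_hz(b - xx, acq)
    a^2 / (a^2 + d^2)
  }
  pos <- numeric(0); amp <- numeric(0); wid <- numeric(0)
  for (k in seq_len(n)) {
    if (max(tr) < noise_floor) break
    e <- .absorption_component(tr, x, acq)
    pos <- c(pos, e$b); amp <- c(amp, e$h); wid <- c(wid, e$w)
    tr <- tr - e$h * lor(e$b, e$w, x)
  }
  # CLEAN-style refinement: re-estimate each component against the
  # residual with the others subtracted, a few sweeps
  nf <- length(pos)
  if (nf) for (s in 1:4) for (j in seq_len(nf)) {
    tr <- tr + amp[j] * lor(pos[j], wid[j], x)
    e <- .absorption_component(tr, x, acq, win = abs(x - pos[j]) < 12)
    if (e$h > noise_floor / 2) {
      pos[j] <- e$b; amp[j] <- e$h; wid[j] <- e$w
    }
    tr <- tr - amp[j] * lor(pos[j], wid[j], x)
  }
  step_ppm <- stats::median(abs(diff(x)))
  if (length(pos) < n) {
    if (!fallback)
      stop("found only ", length(pos), " spectral features for n = ", n,
           " and fallback is disabled")
    warning("fewer spectral features than resonances requested; ",
            "placing the remainder at residual-absorption maxima")
    # sub-floor placement: largest residual absorption values, kept at
    # least three grid steps away from every already placed component
    ord <- order(tr, decreasing = TRUE)
    for (i in ord) {
      if (length(pos) == n) break
      if (!length(pos) || min(abs(x[i] - pos)) > 3 * step_ppm) {
        pos <- c(pos, x[i])
        amp <- c(amp, max(tr[i], 0.01))
        wid <- c(wid, 500)
      }
    }
    # last resort: even spacing across the band
    if (length(pos) < n) {
      fill <- seq(x[1] + diff(range(x)) / (2 * n),
                  x[length(x)] - diff(range(x)) / (2 * n), length.out = n)
      dmin <- vapply(fill, function(f) min(abs(f - pos)), numeric(1))
      fill <- fill[order(dmin, decreasing = TRUE)]
      need <- n - length(pos)
      pos <- c(pos, fill[seq_len(need)])
      amp <- c(amp, rep(0.05, need))
      wid <- c(wid, rep(500, need))
    }
  }
  # distinct positions are required; nudge collisions by half a grid step
  while (anyDuplicated(pos)) {
    j <- which(duplicated(pos))[1]
    pos[j] <- pos[j] + step_ppm / 2
  }
  zspec_params(A0, lapply(seq_len(n), function(i)
    resonance(pos[i], amp[i], wid[i])))
}

#' Fit an n-resonance exponential-Lorentzian model to a z-spectrum
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the product model [evaluate_zspectrum()] against
#' the data. Per-point \code{sigma} values, when present, enter as inverse
#' weights; otherwise unit weights are used. Box constraints keep positions
#' inside the sampled band (+/- 2 ppm), amplitudes in [0, 10] and widths
#' (a/pi) in [10, 5000] Hz by default. Standard errors are taken from the
#' covariance of the converged fit; a singular covariance yields \code{NA}
#' standard errors with a warning. Non-convergence is flagged, not fatal.
#'
#' @param z an \code{xe_zspectrum}.
#' @param n number of resonances.
#' @param init an \code{xe_zspec_params} initial guess (defaults to
#'   [initial_guess()]).
#' @param bounds optional list with elements \code{A}, \code{b}, \code{B},
#'   \code{w}, each \code{c(lower, upper)}; defaults as described.
#' @param acq an \code{xe_acq}.
#' @return An object of class \code{xe_fit}: fields \code{params}
#'   (resonances sorted by decreasing ppm), \code{stderr} (data frame with
#'   columns \code{b_ppm}, \code{B}, \code{width_hz} plus attribute row for
#'   \code{A}), \code{A_stderr}, \code{rss}, \code{criterion} (BIC),
#'   \code{n_resonances}, \code{n_points}, \code{converged}.
#' @export
fit_zspectrum <- function(z, n, init = NULL, bounds = NULL,
                          acq = acquisition_params()) {
  stopifnot(inherits(z, "xe_zspectrum"))
  n <- as.integer(n)
  if (is.null(init)) init <- initial_guess(z, n, acq)
  stopifnot(inherits(init, "xe_zspec_params"))
  if (length(init$resonances) != n)
    stop("initial guess has ", length(init$resonances),
         " resonances but n = ", n)
  b0 <- .default_bounds(z)
  if (!is.null(bounds)) b0 <- modifyList(b0, bounds)
  lower <- c(b0$A[1], rep(b0$b[1], n), rep(b0$B[1], n), rep(b0$w[1], n))
  upper <- c(b0$A[2], rep(b0$b[2], n), rep(b0$B[2], n), rep(b0$w[2], n))
  p0 <- pmin(pmax(.pack(init), lower), upper)

  w <- if (!is.null(z$sigma)) 1 / z$sigma else rep(1, length(z$offsets))
  y <- z$intensities
  cc <- 2 * pi * acq$f_obs * 1e-6   # ppm -> rad/s
  resid_fn <- function(p) {
    (.eval_raw(p, n, z$offsets, acq) - y) * w
  }
  # analytic Jacobian of the weighted residuals in c(A, b, B, w) order
  jac_fn <- function(p) {
    b <- p[1 + seq_len(n)]
    B <- p[1 + n + seq_len(n)]
    a <- pi * p[1 + 2 * n + seq_len(n)]
    d <- cc * outer(z$offsets, b, function(x, bb) bb - x)
    L <- 1 / (1 + sweep(d^2, 2, a^2, "/"))
    S <- p[1] * exp(-drop(L %*% B))
    J <- matrix(0, length(z$offsets), length(p))
    J[, 1] <- S / p[1]
    SW <- S * w
    for (i in seq_len(n)) {
      J[, 1 + i] <- SW * B[i] * 2 * cc * d[, i] * L[, i]^2 / a[i]^2
      J[, 1 + n + i] <- -SW * L[, i]
      J[, 1 + 2 * n + i] <- -SW * B[i] * pi * 2 * d[, i]^2 * L[, i]^2 / a[i]^3
    }
    J[, 1] <- J[, 1] * w
    J
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 100000,
                                         ftol = 1e-14, ptol = 1e-14, gtol = 0))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  npts <- length(y)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit did not converge (", fit$message, "); parameters reported anyway")

  se <- rep(NA_real_, length(p))
  dof <- npts - length(p)
  if (dof > 0) {
    cv <- try(chol2inv(chol(fit$hessian)) * 2 * rss / dof, silent = TRUE)
    if (inherits(cv, "try-error") || any(!is.finite(diag(cv))) ||
        any(diag(cv) < 0)) {
      warning("singular covariance; standard errors set to NA")
    } else {
      se <- sqrt(diag(cv))
    }
  }

  params <- .unpack(p, n)
  # align stderr rows with the decreasing-ppm ordering inside params
  ord <- order(p[1 + seq_len(n)], decreasing = TRUE)
  stderr <- data.frame(b_ppm = se[1 + seq_len(n)][ord],
                       B = se[1 + n + seq_len(n)][ord],
                       width_hz = se[1 + 2 * n + seq_len(n)][ord])
  k <- length(p)
  # Gaussian-noise BIC: when per-point sigma is known the weighted rss is a
  # chi-square and enters the likelihood directly; without sigma the noise
  # variance is profiled out
  bic <- if (!is.null(z$sigma)) rss + k * log(npts)
    else npts * log(rss / npts) + k * log(npts)
  structure(list(params = params, stderr = stderr, A_stderr = se[1],
                 rss = rss, criterion = bic, n_resonances = n,
                 n_points = npts, converged = converged,
                 weighted = !is.null(z$sigma)),
            class = "xe_fit")
}

#' @export
print.xe_fit <- function(x, ...) {
  cat(sprintf("%d-resonance z-spectrum fit (%s), rss = %.4g, BIC = %.2f\n",
              x$n_resonances, if (x$converged) "converged" else "NOT converged",
              x$rss, x$criterion))
  cat(sprintf("A = %.4g (+/- %.2g)\n", x$params$A, x$A_stderr))
  df <- as.data.frame(x$params)
  names(df) <- c("b_ppm", "B", "width_hz")
  se <- x$stderr
  out <- data.frame(b_ppm = sprintf("%.1f +/- %.1f", df$b_ppm, se$b_ppm),
                    B = sprintf("%.3f +/- %.3f", df$B, se$B),
                    width_hz = sprintf("%.0f +/- %.0f", df$width_hz, se$width_hz))
  print(out, row.names = FALSE)
  invisible(x)
}

# warm start for n components: the best (n-1)-component fit plus one
# component placed at the maximum of its residual absorption
.increment_init <- function(prev_fit, z, acq) {
  yhat <- evaluate_zspectrum(prev_fit$params, z$offsets, acq)
  tr <- -log(pmax(pmin(z$intensities / yhat, 1), 1e-10))
  e <- .absorption_component(tr, z$offsets, acq)
  res <- c(prev_fit$params$resonances, list(resonance(e$b, e$h, e$w)))
  b <- vapply(res, `[[`, numeric(1), "b")
  while (anyDuplicated(b)) {
    j <- which(duplicated(b))[1]
    res[[j]]$b <- res[[j]]$b + 0.1
    b <- vapply(res, `[[`, numeric(1), "b")
  }
  zspec_params(prev_fit$params$A, res)
}

# warm start for n components: the best (n-1)-fit with its "largest"
# component (amplitude x width) split into two half-amplitude copies
.split_init <- function(prev_fit, z, acq) {
  res <- prev_fit$params$resonances
  size <- vapply(res, function(r) r$B * width_hz(r), numeric(1))
  j <- which.max(size)
  r <- res[[j]]
  w <- width_hz(r)
  dppm <- hz_to_ppm(w / 2, acq)
  res[[j]] <- resonance(r$b - dppm, r$B / 2, max(w / 2, 10))
  res <- c(res, list(resonance(r$b + dppm, r$B / 2, max(w / 2, 10))))
  b <- vapply(res, `[[`, numeric(1), "b")
  while (anyDuplicated(b)) {
    k <- which(duplicated(b))[1]
    res[[k]]$b <- res[[k]]$b + 0.1
    b <- vapply(res, `[[`, numeric(1), "b")
  }
  zspec_params(prev_fit$params$A, res)
}

# replace degenerate "ghost" components (near-bound amplitude with a width
# far below the grid step, hence no spectral footprint) by residual-driven
# components
.deghost_init <- function(fit, z, acq) {
  step_hz <- ppm_to_hz(stats::median(abs(diff(z$offsets))), acq)
  res <- fit$params$resonances
  ghost <- vapply(res, function(r) width_hz(r) < step_hz / 4 && r$B > 2,
                  logical(1))
  if (!any(ghost)) return(NULL)
  base <- fit
  base$params <- zspec_params(fit$params$A, res[!ghost])
  ini <- base$params
  for (i in seq_len(sum(ghost)))
    ini <- .increment_init(list(params = ini), z, acq)
  ini
}

# warm start for n components: the best (n+1)-fit with its weakest
# component (smallest signal area) removed
.decrement_init <- function(next_fit) {
  res <- next_fit$params$resonances
  if (length(res) < 2L) return(NULL)
  area <- vapply(res, function(r) r$B * width_hz(r), numeric(1))
  zspec_params(next_fit$params$A, res[-which.min(area)])
}

# merge the two most mutually overlapping components into one and regrow
# the freed component from the residual; counters split-dominant optima
.merge_init <- function(fit, z, acq) {
  res <- fit$params$resonances
  if (length(res) < 2L) return(NULL)
  b <- vapply(res, `[[`, numeric(1), "b")
  w <- vapply(res, width_hz, numeric(1))
  w_ppm <- hz_to_ppm(w, acq)
  overlap <- -Inf; pair <- NULL
  for (i in seq_along(res)[-1]) for (j in seq_len(i - 1)) {
    ov <- (w_ppm[i] + w_ppm[j]) / 2 - abs(b[i] - b[j])
    if (ov > overlap) { overlap <- ov; pair <- c(i, j) }
  }
  if (overlap < 0) return(NULL)
  r1 <- res[[pair[1]]]; r2 <- res[[pair[2]]]
  a1 <- r1$B * width_hz(r1); a2 <- r2$B * width_hz(r2)
  merged <- resonance((r1$b * a1 + r2$b * a2) / (a1 + a2),
                      r1$B + r2$B,
                      (width_hz(r1) * a1 + width_hz(r2) * a2) / (a1 + a2))
  keep <- res[-pair]
  ini <- zspec_params(fit$params$A, c(keep, list(merged)))
  .increment_init(list(params = ini), z, acq)
}

# jitter an initial guess for multi-start fitting; band clipping happens in
# fit_zspectrum via the bounds
.perturb_init <- function(init, band, scale = 1) {
  res <- lapply(init$resonances, function(r) {
    resonance(min(max(r$b + stats::rnorm(1, 0, 1.5 * scale), band[1]), band[2]),
              r$B * exp(stats::rnorm(1, 0, 0.3 * scale)),
              min(max(width_hz(r) * exp(stats::rnorm(1, 0, 0.3 * scale)), 10),
                  5000))
  })
  b <- vapply(res, `[[`, numeric(1), "b")
  while (anyDuplicated(b)) {
    j <- which(duplicated(b))[1]
    res[[j]]$b <- res[[j]]$b + 0.1
    b <- vapply(res, `[[`, numeric(1), "b")
  }
  zspec_params(init$A * exp(stats::rnorm(1, 0, 0.05)), res)
}

#' Choose the number of resonances by information criterion
#'
#' Fits every resonance count in \code{n_range}, each with a multi-start
#' strategy (the deterministic [initial_guess()] plus seeded random
#' perturbations of it), keeps the best residual sum of squares per count,
#' and selects the count minimizing the Bayesian information criterion
#' under a Gaussian noise model,
#' \code{BIC = n_pts * log(rss/n_pts) + k * log(n_pts)} with
#' \code{k = 3n + 1} free parameters. All per-count scores are retained in
#' the result (\code{$selection}).
#'
#' @param z an \code{xe_zspectrum}.
#' @param n_range integer vector of candidate resonance counts, within
#'   1..10.
#' @param acq an \code{xe_acq}.
#' @param n_starts restarts per count (first start is unperturbed).
#' @param seed integer master seed for the restart perturbations; all
#'   randomness flows through it.
#' @return the best \code{xe_fit}, with the score table attached as
#'   \code{$selection}.
#' @export
select_model <- function(z, n_range, acq = acquisition_params(),
                         n_starts = 8, seed = 1) {
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 1) || any(n_range > 10))
    stop("n_range must lie within [1, 10]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  band <- range(z$offsets)
  # deterministic incremental chain: grow a fit one component at a time,
  # polishing at every step; robust against baseline-warp local optima
  chain <- vector("list", max(n_range))
  prev_c <- NULL
  for (k in seq_len(max(n_range))) {
    cand <- if (is.null(prev_c)) {
      list(try(suppressWarnings(initial_guess(z, 1, acq)), silent = TRUE))
    } else {
      list(try(suppressWarnings(.increment_init(prev_c, z, acq)),
               silent = TRUE),
           try(suppressWarnings(.split_init(prev_c, z, acq)), silent = TRUE))
    }
    fc <- NULL
    for (ini in cand) {
      if (inherits(ini, "try-error")) next
      f <- try(suppressWarnings(fit_zspectrum(z, k, ini, acq = acq)),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(fc) || f$rss < fc$rss) fc <- f
    }
    if (is.null(fc)) break
    chain[[k]] <- fc
    prev_c <- fc
  }
  fits <- list()
  prev <- NULL
  for (n in n_range) {
    init0 <- try(suppressWarnings(initial_guess(z, n, acq)), silent = TRUE)
    if (inherits(init0, "try-error")) init0 <- NULL
    inits <- list()
    if (!is.null(init0)) {
      inits <- c(inits, list(init0))
      while (length(inits) < n_starts)
        inits <- c(inits, list(.perturb_init(
          init0, band, scale = if (length(inits) %% 2) 1 else 2.5)))
    }
    # warm starts grown from the best (n-1)-component fit (chain or range
    # predecessor): one appends a component at the residual-absorption
    # maximum, one splits the largest existing component
    warm <- if (n > 1L && length(chain) >= n - 1L && !is.null(chain[[n - 1L]]))
      chain[[n - 1L]] else prev
    if (!is.null(warm) && warm$n_resonances == n - 1L) {
      for (mk in list(.increment_init, .split_init)) {
        ini <- try(suppressWarnings(mk(warm, z, acq)), silent = TRUE)
        if (!inherits(ini, "try-error")) {
          inits <- c(inits, list(ini))
          inits <- c(inits, lapply(seq_len(2), function(i)
            .perturb_init(ini, band)))
        }
      }
    }
    # jittered restarts of the chain fit at this count
    if (length(chain) >= n && !is.null(chain[[n]]))
      inits <- c(inits, lapply(seq_len(2), function(i)
        .perturb_init(chain[[n]]$params, band)))
    best <- if (length(chain) >= n) chain[[n]] else NULL
    for (init in inits) {
      f <- try(suppressWarnings(fit_zspectrum(z, n, init, acq = acq)),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || (f$converged && !best$converged) ||
          (f$converged == best$converged && f$rss < best$rss)) best <- f
    }
    if (!is.null(best)) {
      # structural repair moves on the winner: de-ghost parked spikes and
      # merge split components, keeping a repair when it lowers the
      # residual; iterate a couple of times
      for (rep_round in 1:2) {
        improved <- FALSE
        for (mk in list(.deghost_init, .merge_init)) {
          ini <- try(suppressWarnings(mk(best, z, acq)), silent = TRUE)
          if (inherits(ini, "try-error") || is.null(ini)) next
          f <- try(suppressWarnings(fit_zspectrum(z, n, ini, acq = acq)),
                   silent = TRUE)
          if (!inherits(f, "try-error") && f$rss < best$rss) {
            best <- f
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      fits[[as.character(n)]] <- best
      prev <- best
    }
  }
  # backward pruning pass: re-seed each count from the next-larger fit
  # with its weakest component dropped; cures counts that got stuck while
  # their larger neighbour found the true structure
  for (n in rev(n_range[-length(n_range)])) {
    up <- fits[[as.character(n + 1L)]]
    if (is.null(up)) next
    ini <- try(suppressWarnings(.decrement_init(up)), silent = TRUE)
    if (inherits(ini, "try-error") || is.null(ini) ||
        length(ini$resonances) != n) next
    f <- try(suppressWarnings(fit_zspectrum(z, n, ini, acq = acq)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    cur <- fits[[as.character(n)]]
    if (is.null(cur) || f$rss < cur$rss) fits[[as.character(n)]] <- f
  }
  if (!length(fits)) stop("no resonance count in n_range could be fitted")
  sel <- data.frame(
    n = as.integer(names(fits)),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    bic = vapply(fits, `[[`, numeric(1), "criterion"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  best <- fits[[which.min(sel$bic)]]
  best$selection <- sel[order(sel$n), ]
  rownames(best$selection) <- NULL
  best
}

#' Index of the most intense resonance of a fit
#'
#' The intensity of a CEST resonance scales with its signal area, the
#' product of exponential amplitude and width. Ranking by area rather than
#' by amplitude alone is robust against degenerate narrow components that
#' a fit may park between grid points (large B, negligible width, no
#' spectral footprint).
#'
#' @param fit an \code{xe_fit}.
#' @return integer row index into [fit_table()].
#' @export
dominant_resonance <- function(fit) {
  stopifnot(inherits(fit, "xe_fit"))
  tab <- as.data.frame(fit$params)
  which.max(tab$B * tab$width_hz)
}

#' Export a fit as a plain parameter table
#'
#' @param fit an \code{xe_fit}.
#' @return data frame with columns \code{b_ppm}, \code{B}, \code{width_hz}
#'   and their standard errors, resonances ordered downfield to upfield.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "xe_fit"))
  df <- as.data.frame(fit$params)
  data.frame(b_ppm = df$b_ppm, b_ppm_se = fit$stderr$b_ppm,
             B = df$B, B_se = fit$stderr$B,
             width_hz = df$width_hz, width_hz_se = fit$stderr$width_hz)
}

#' Write or read fit results as JSON
#'
#' The JSON mirrors the reported parameter layout: the baseline \code{A}
#' and, per resonance, position (ppm), amplitude \code{B}, and width
#' (a/pi, Hz), each with its standard error.
#'
#' @param fit an \code{xe_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "xe_fit"))
  obj <- list(A = fit$params$A, A_se = fit$A_stderr,
              n_resonances = fit$n_resonances,
              rss = fit$rss, bic = fit$criterion,
              converged = fit$converged,
              resonances = fit_table(fit))
  if (!is.null(fit$selection)) obj$selection <- fit$selection
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
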