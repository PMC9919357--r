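#' @importFrom stats approx coef median optim quantile rnorm runif sd setNames
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

# ---- constructors ----------------------------------------------------------

#' Create a single CEST resonance
#'
#' A resonance of the exponential-Lorentzian z-spectrum model is described by
#' its chemical-shift position \code{b} (ppm, referenced to xenon gas at
#' 0 ppm), a dimensionless exponential amplitude \code{B} (the saturation
#' depth on resonance is \code{1 - exp(-B)} relative to baseline) and an
#' angular half-width \code{a} in rad/s. Widths are exchanged with the user
#' as \code{a/pi} in Hz, the convention used for reported line widths; the
#' conversion is exact.
#'
#' @param b_ppm chemical-shift position in ppm.
#' @param B dimensionless exponential amplitude, must be >= 0.
#' @param width_hz half-width expressed as \code{a/pi} in Hz, must be > 0.
#' @return An object of class \code{xe_resonance} with fields \code{b}
#'   (ppm), \code{B}, and \code{a} (rad/s).
#' @examples
#' r <- resonance(77.5, 2.3, 573)
#' width_hz(r)  # 573, exactly
#' @export
resonance <- function(b_ppm, B, width_hz) {
  stopifnot(is.numeric(b_ppm), length(b_ppm) == 1L, is.finite(b_ppm))
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 0)
    stop("amplitude B must be a finite number >= 0")
  if (!is.numeric(width_hz) || length(width_hz) != 1L ||
      !is.finite(width_hz) || width_hz <= 0)
    stop("width (a/pi, Hz) must be a finite number > 0")
  structure(list(b = b_ppm, B = B, a = pi * width_hz),
            class = "xe_resonance")
}

#' Reported half-width of a resonance
#'
#' Returns the half-width as \code{a/pi} in Hz, the unit in which line
#' widths are reported. The internal storage is angular (rad/s); the
#' round-trip is exact.
#'
#' @param r an \code{xe_resonance}.
#' @return numeric scalar, Hz.
#' @export
width_hz <- function(r) {
  stopifnot(inherits(r, "xe_resonance"))
  r$a / pi
}

#' Parameter set of the multi-resonance z-spectrum model
#'
#' Bundles the baseline amplitude \code{A} (normalized free-xenon signal far
#' off resonance) with an ordered list of resonances. Resonances are stored
#' sorted by decreasing ppm, i.e. numbered in order of appearance upfield
#' toward the free-xenon line. Degenerate positions are rejected: two
#' resonances at the same ppm are not identifiable.
#'
#' @param A baseline amplitude, must be > 0.
#' @param resonances list of \code{xe_resonance} objects (may be empty).
#' @return An object of class \code{xe_zspec_params}.
#' @export
zspec_params <- function(A, resonances = list()) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("baseline amplitude A must be a finite number > 0")
  if (inherits(resonances, "xe_resonance")) resonances <- list(resonances)
  ok <- vapply(resonances, inherits, logical(1), what = "xe_resonance")
  if (!all(ok)) stop("resonances must be a list of xe_resonance objects")
  b <- vapply(resonances, `[[`, numeric(1), "b")
  if (anyDuplicated(b)) stop("degenerate resonance positions (equal ppm) are not allowed")
  structure(list(A = A, resonances = resonances[order(b, decreasing = TRUE)]),
            class = "xe_zspec_params")
}

#' @export
print.xe_zspec_params <- function(x, ...) {
  cat(sprintf("z-spectrum model: A = %.4g, %d resonance(s)\n",
              x$A, length(x$resonances)))
  if (length(x$resonances)) {
    df <- as.data.frame(x)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.xe_zspec_params <- function(x, ...) {
  data.frame(
    b_ppm    = vapply(x$resonances, `[[`, numeric(1), "b"),
    B        = vapply(x$resonances, `[[`, numeric(1), "B"),
    width_hz = vapply(x$resonances, width_hz, numeric(1))
  )
}

#' CEST acquisition settings
#'
#' Describes the saturation block and frequency axis of a hyperCEST
#' experiment: RF nutation frequency, saturation duration, the 129Xe
#' observe frequency used to convert ppm to Hz, the position of freely
#' dissolved xenon, and the irradiation grid. The grid is stored in Hz
#' relative to the free-xenon line, positive values downfield (larger ppm).
#'
#' The defaults mirror a weak continuous-wave saturation scheme on a 7 T
#' instrument: nutation frequency 2*pi*99 rad/s applied for 20 s, offsets
#' stepped from 5 kHz downfield to 13 kHz upfield of the free-xenon line in
#' 200 Hz steps (91 points). The observe frequency defaults to 83.0 MHz
#' (129Xe at 7 T) and should be overridden to match the instrument.
#'
#' @param omega1 RF nutation angular frequency, rad/s (>= 0).
#' @param t_sat saturation duration, s (> 0).
#' @param f_obs 129Xe observe frequency, Hz (> 0).
#' @param ref_free_xe_ppm position of freely dissolved xenon, ppm.
#' @param grid_start_hz,grid_stop_hz,grid_step_hz irradiation offset grid in
#'   Hz relative to the free-xenon line; \code{grid_step_hz} must be > 0.
#' @return An object of class \code{xe_acq}.
#' @export
acquisition_params <- function(omega1 = 2 * pi * 99,
                               t_sat = 20,
                               f_obs = 83.0e6,
                               ref_free_xe_ppm = 196,
                               grid_start_hz = 5000,
                               grid_stop_hz = -13000,
                               grid_step_hz = 200) {
  if (!is.numeric(omega1) || omega1 < 0) stop("omega1 must be >= 0")
  if (!is.numeric(t_sat) || t_sat <= 0) stop("t_sat must be > 0")
  if (!is.numeric(f_obs) || f_obs <= 0) stop("f_obs must be > 0")
  if (!is.numeric(grid_step_hz) || grid_step_hz <= 0) stop("grid step must be > 0")
  structure(list(omega1 = omega1, t_sat = t_sat, f_obs = f_obs,
                 ref_free_xe_ppm = ref_free_xe_ppm,
                 grid_start_hz = grid_start_hz,
                 grid_stop_hz = grid_stop_hz,
                 grid_step_hz = grid_step_hz),
            class = "xe_acq")
}

#' Irradiation grid of an acquisition, in ppm
#'
#' Expands the stored (start, stop, step) offset grid, given in Hz relative
#' to the free-xenon line, into absolute irradiation positions in ppm,
#' sorted ascending.
#'
#' @param acq an \code{xe_acq}.
#' @return numeric vector of ppm positions.
#' @export
acq_grid_ppm <- function(acq) {
  stopifnot(inherits(acq, "xe_acq"))
  hz <- seq(acq$grid_start_hz, acq$grid_stop_hz,
            by = -sign(acq$grid_start_hz - acq$grid_stop_hz) * acq$grid_step_hz)
  if (!length(hz)) stop("empty irradiation grid")
  sort(acq$ref_free_xe_ppm + hz_to_ppm(hz, acq))
}

#' Xenon exchange and relaxation parameters
#'
#' Mechanistic description of one CEST resonance: the pseudo-first-order
#' rate of xenon entering the host cage (\code{k_on}), the rate of leaving
#' it (\code{k_off}), and the transverse relaxation rate of host-bound
#' xenon (\code{R2}). All rates in 1/s, all >= 0.
#'
#' @param k_on,k_off,R2 rates in 1/s.
#' @return An object of class \code{xe_exchange}.
#' @export
exchange_params <- function(k_on, k_off, R2) {
  for (v in list(k_on = k_on, k_off = k_off, R2 = R2))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("exchange rates must be finite numbers >= 0")
  structure(list(k_on = k_on, k_off = k_off, R2 = R2), class = "xe_exchange")
}

# ---- unit conversion -------------------------------------------------------

#' Convert chemical-shift differences between ppm and Hz
#'
#' \code{ppm_to_hz} maps a shift in ppm to Hz through the observe frequency:
#' \code{hz = x * f_obs * 1e-6}; \code{hz_to_ppm} is the exact inverse.
#' These convert shift *differences*; absolute referencing (the free-xenon
#' line) is handled by the acquisition grid.
#'
#' @param x shift in ppm (or Hz for the inverse).
#' @param acq an \code{xe_acq} supplying \code{f_obs}.
#' @return numeric vector.
#' @export
ppm_to_hz <- function(x, acq) {
  stopifnot(inherits(acq, "xe_acq"))
  x * acq$f_obs * 1e-6
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(x, acq) {
  stopifnot(inherits(acq, "xe_acq"))
  x / (acq$f_obs * 1e-6)
}

# ---- forward model ---------------------------------------------------------

# Lorentzian factors L_i(x) = a_i^2 / (a_i^2 + (b_i - x)^2), offsets in ppm,
# widths angular; returns n_offsets x n_resonances matrix.
.lorentz_matrix <- function(params, offsets_ppm, acq) {
  b <- vapply(params$resonances, `[[`, numeric(1), "b")
  a <- vapply(params$resonances, `[[`, numeric(1), "a")
  if (any(a <= 0)) stop("resonance half-widths must be > 0")
  # ppm difference -> angular frequency difference (rad/s)
  d <- 2 * pi * ppm_to_hz(outer(offsets_ppm, b, function(x, bb) bb - x), acq)
  1 / (1 + sweep(d^2, 2, a^2, "/"))
}

#' Evaluate the exponential-Lorentzian z-spectrum model
#'
#' The saturation response at irradiation position \code{x} (ppm) is the
#' product model
#' \deqn{S(x) = A \prod_i \exp\!\left(-B_i \frac{a_i^2}{a_i^2 + (b_i - x)^2}\right)}
#' with the position difference converted from ppm to angular frequency
#' (rad/s) via the observe frequency. An empty resonance list gives the
#' flat baseline \code{A}. The model satisfies \code{0 < S(x) <= A} for all
#' finite offsets and is invariant under permutation of the resonance list.
#'
#' @param params an \code{xe_zspec_params}.
#' @param offsets_ppm numeric vector of irradiation positions, ppm.
#' @param acq an \code{xe_acq} (only \code{f_obs} is used).
#' @return numeric vector of model intensities, same length as
#'   \code{offsets_ppm}.
#' @export
evaluate_zspectrum <- function(params, offsets_ppm, acq = acquisition_params()) {
  stopifnot(inherits(params, "xe_zspec_params"))
  if (!is.numeric(offsets_ppm) || !all(is.finite(offsets_ppm)))
    stop("offsets must be finite numbers")
  if (!length(params$resonances))
    return(rep(params$A, length(offsets_ppm)))
  L <- .lorentz_matrix(params, offsets_ppm, acq)
  B <- vapply(params$resonances, `[[`, numeric(1), "B")
  params$A * exp(-drop(L %*% B))
}

#' Mixed exact/linearized z-spectrum evaluation
#'
#' Keeps the exact exponential for the strongest resonance (largest
#' \code{B}) and expands the remaining exponentials to first order, so that
#' weak signals appear as Lorentzians reflected at the baseline:
#' \deqn{S(x) \approx A\, e^{-B_s L_s(x)} \left(1 - \sum_{i \neq s} B_i L_i(x)\right).}
#' The approximation is accurate when every non-dominant \code{B_i} is well
#' below 1 (error bounded by the quadratic Taylor remainder of the
#' exponential); a warning is emitted when some non-dominant amplitude is
#' >= 1.
#'
#' @inheritParams evaluate_zspectrum
#' @return numeric vector of model intensities.
#' @export
evaluate_zspectrum_linearized <- function(params, offsets_ppm,
                                          acq = acquisition_params()) {
  stopifnot(inherits(params, "xe_zspec_params"))
  if (!is.numeric(offsets_ppm) || !all(is.finite(offsets_ppm)))
    stop("offsets must be finite numbers")
  if (!length(params$resonances))
    return(rep(params$A, length(offsets_ppm)))
  B <- vapply(params$resonances, `[[`, numeric(1), "B")
  s <- which.max(B)
  if (length(B) > 1L && any(B[-s] >= 1))
    warning("linearized evaluation with non-dominant amplitude B >= 1; accuracy loss")
  L <- .lorentz_matrix(params, offsets_ppm, acq)
  weak <- if (length(B) > 1L) drop(L[, -s, drop = FALSE] %*% B[-s]) else 0
  params$A * exp(-B[s] * L[, s]) * (1 - weak)
}

# ---- exchange-mechanistic mapping ------------------------------------------

#' CEST resonance amplitude from exchange parameters
#'
#' Maps xenon exchange and relaxation rates, under given saturation
#' settings, to the exponential amplitude of the resulting CEST resonance:
#' \deqn{B = t_{sat}\, k_{on} \frac{\omega_1^2}{\omega_1^2 + k_{off}^2 + k_{off} R_2}.}
#' The amplitude is linear in both the saturation time and the on-rate and
#' vanishes without RF (\code{omega1 = 0}) or without exchange into the
#' host (\code{k_on = 0}).
#'
#' @param ex an \code{xe_exchange}.
#' @param acq an \code{xe_acq} supplying \code{omega1} and \code{t_sat}.
#' @return dimensionless amplitude B >= 0.
#' @export
cest_amplitude <- function(ex, acq = acquisition_params()) {
  stopifnot(inherits(ex, "xe_exchange"), inherits(acq, "xe_acq"))
  den <- acq$omega1^2 + ex$k_off^2 + ex$k_off * ex$R2
  if (den == 0) {
    if (ex$k_on == 0) return(0)  # 0 * (0/0): no RF, no exchange -> no effect
    stop("degenerate exchange parameters: omega1 = k_off = 0 gives an undefined amplitude")
  }
  acq$t_sat * ex$k_on * acq$omega1^2 / den
}

#' CEST resonance half-width from exchange parameters
#'
#' The angular half-width of a CEST resonance combines RF power, exchange
#' and bound-pool relaxation as
#' \deqn{a^2 = \left(\omega_1^2 + k_{off}(k_{off} + R_2)\right)
#'             \frac{k_{off} + R_2}{k_{off}}
#'           = \omega_1^2 + k_{off}^2 + R_2^2
#'             + \frac{R_2}{k_{off}}\left(\omega_1^2 + 2 k_{off}^2\right).}
#' Without exchange broadening or relaxation (\code{k_off = R2 = 0}) the
#' width reduces to the RF nutation frequency itself, \code{a = omega1}.
#' The width grows without bound as \code{k_off} tends to 0 with
#' \code{R2 > 0}; that corner is rejected.
#'
#' @inheritParams cest_amplitude
#' @return angular half-width a in rad/s (divide by pi for the reported
#'   width in Hz).
#' @seealso [width_high_power_limit()] for the strong-RF simplification.
#' @export
cest_width <- function(ex, acq = acquisition_params()) {
  stopifnot(inherits(ex, "xe_exchange"), inherits(acq, "xe_acq"))
  if (acq$omega1 == 0 && ex$k_off == 0 && ex$R2 == 0)
    stop("all of omega1, k_off, R2 are zero: width undefined")
  relax <- if (ex$R2 == 0) 0 else {
    if (ex$k_off == 0)
      stop("k_off = 0 with R2 > 0 gives an unbounded width")
    ex$R2^2 + (ex$R2 / ex$k_off) * (acq$omega1^2 + 2 * ex$k_off^2)
  }
  sqrt(acq$omega1^2 + ex$k_off^2 + relax)
}

#' High-RF-power limit of the CEST width
#'
#' When the RF amplitude dominates the exchange rate
#' (\code{omega1 >> k_off}) the width expression simplifies to
#' \deqn{a \approx \sqrt{\omega_1^2 + R_2^2 + \frac{R_2}{k_{off}} \omega_1^2},}
#' the regime in which bound-pool relaxation, rather than exchange, sets
#' the line width. A warning is emitted when \code{k_off} is not small
#' against \code{omega1}.
#'
#' @inheritParams cest_amplitude
#' @return angular half-width a in rad/s.
#' @export
width_high_power_limit <- function(ex, acq = acquisition_params()) {
  stopifnot(inherits(ex, "xe_exchange"), inherits(acq, "xe_acq"))
  if (acq$omega1 == 0 && ex$k_off == 0 && ex$R2 == 0)
    stop("all of omega1, k_off, R2 are zero: width undefined")
  if (acq$omega1 > 0 && ex$k_off > 0.25 * acq$omega1)
    warning("k_off is comparable to omega1; the high-power simplification degrades")
  relax <- if (ex$R2 == 0) 0 else {
    if (ex$k_off == 0)
      stop("k_off = 0 with R2 > 0 gives an unbounded width")
    ex$R2^2 + (ex$R2 / ex$k_off) * acq$omega1^2
  }
  sqrt(acq$omega1^2 + relax)
}

#' Xenon off-rate from an observed line width
#'
#' In slow-exchange host-guest systems the line width of bound xenon is
#' dominated by exchange broadening, so the observed width reads out the
#' rate of xenon leaving the host. Two conventions are supported:
#' \describe{
#'   \item{\code{"numeric"}}{\code{k_off = fwhm_hz} in 1/s, reading a
#'     width quoted in Hz directly as a rate. Default, matching how such
#'     exchange rates are usually quoted for cryptophane systems (a
#'     320 Hz line in lipids versus 24 Hz in water corresponds to off-rates
#'     of 320/s and 24/s).}
#'   \item{\code{"lorentzian"}}{\code{k_off = pi * fwhm_hz}, the exact
#'     Lorentzian relation FWHM = k_off/pi for pure exchange broadening.}
#' }
#'
#' @param fwhm_hz full width at half maximum, Hz (> 0).
#' @param convention "numeric" (default) or "lorentzian".
#' @return off-rate in 1/s.
#' @export
koff_from_linewidth <- function(fwhm_hz, convention = c("numeric", "lorentzian")) {
  if (!is.numeric(fwhm_hz) || any(fwhm_hz <= 0)) stop("fwhm_hz must be > 0")
  convention <- match.arg(convention)
  switch(convention,
         numeric = fwhm_hz,
         lorentzian = pi * fwhm_hz)
}
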