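# ---- containers ------------------------------------------------------------

#' A single direct-detection 1-D spectrum from a CEST series
#'
#' One absorption-mode spectrum acquired after saturation at a given
#' irradiation offset. The ppm axis must be strictly monotone.
#'
#' @param axis_ppm ppm grid of the spectrum, strictly monotone.
#' @param amplitude real absorption-mode intensities.
#' @param irradiation_offset_ppm the saturation position applied before
#'   this scan, ppm.
#' @return An object of class \code{xe_scan1d}.
#' @export
scan1d <- function(axis_ppm, amplitude, irradiation_offset_ppm) {
  stopifnot(is.numeric(axis_ppm), is.numeric(amplitude),
            length(axis_ppm) == length(amplitude))
  d <- diff(axis_ppm)
  if (!length(d) || !(all(d > 0) || all(d < 0)))
    stop("scan axis must be strictly monotone")
  stopifnot(is.numeric(irradiation_offset_ppm),
            length(irradiation_offset_ppm) == 1L)
  structure(list(axis = axis_ppm, amplitude = amplitude,
                 irradiation_offset = irradiation_offset_ppm),
            class = "xe_scan1d")
}

#' A z-spectrum
#'
#' Saturation response sampled over irradiation offsets: normalized (or
#' raw) free-xenon signal versus the saturation position in ppm. Offsets
#' are stored sorted ascending.
#'
#' @param offsets_ppm irradiation positions, ppm; must be distinct.
#' @param intensities signal values, finite.
#' @param sigma optional per-point noise estimate (same length), or NULL.
#' @param meta optional named list of metadata (acquisition settings,
#'   normalization records).
#' @return An object of class \code{xe_zspectrum}.
#' @export
zspectrum <- function(offsets_ppm, intensities, sigma = NULL, meta = list()) {
  stopifnot(is.numeric(offsets_ppm), is.numeric(intensities),
            length(offsets_ppm) == length(intensities))
  if (!all(is.finite(offsets_ppm)) || !all(is.finite(intensities)))
    stop("offsets and intensities must be finite")
  if (anyDuplicated(offsets_ppm)) stop("duplicate irradiation offsets")
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == length(offsets_ppm))
    if (any(sigma <= 0)) stop("sigma must be > 0 where given")
  }
  o <- order(offsets_ppm)
  structure(list(offsets = offsets_ppm[o], intensities = intensities[o],
                 sigma = if (!is.null(sigma)) sigma[o] else NULL,
                 meta = meta),
            class = "xe_zspectrum")
}

#' @export
print.xe_zspectrum <- function(x, ...) {
  cat(sprintf("z-spectrum: %d points, %.1f .. %.1f ppm, intensity %.3g .. %.3g\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
as.data.frame.xe_zspectrum <- function(x, ...) {
  df <- data.frame(offset_ppm = x$offsets, intensity = x$intensities)
  if (!is.null(x$sigma)) df$sigma <- x$sigma
  df
}

# ---- operations ------------------------------------------------------------

#' Integrate a 1-D scan over a window centered on its maximum
#'
#' Integrates the absorption-mode amplitude by the trapezoidal rule over a
#' window of \code{window_ppm} (default 7 ppm) centered on the position of
#' maximum signal amplitude. If the window extends past the sampled axis it
#' is clipped, with a warning. Optionally the peak is located after 3-point
#' running-median smoothing, a robustness knob that is off by default.
#'
#' @param scan an \code{xe_scan1d}.
#' @param window_ppm integration window width in ppm (> 0).
#' @param center optional fixed window center in ppm; by default the window
#'   re-centers on each scan's own amplitude maximum.
#' @param smooth_peak logical; locate the maximum on a 3-point median
#'   smoothed copy of the amplitudes.
#' @return the integral (amplitude x ppm).
#' @export
integrate_scan <- function(scan, window_ppm = 7, center = NULL,
                           smooth_peak = FALSE) {
  stopifnot(inherits(scan, "xe_scan1d"))
  if (!is.numeric(window_ppm) || window_ppm <= 0) stop("window_ppm must be > 0")
  amp <- scan$amplitude
  if (!all(is.finite(amp))) stop("non-finite amplitudes")
  if (all(amp == 0)) stop("all-zero spectrum: no maximum to center on")
  if (is.null(center)) {
    a <- if (smooth_peak) stats::runmed(amp, 3) else amp
    idx <- which(a == max(a))
    center <- scan$axis[idx[ceiling(length(idx) / 2)]]  # middle of ties
  }
  lo <- center - window_ppm / 2
  hi <- center + window_ppm / 2
  ax <- scan$axis
  if (ax[1] > ax[length(ax)]) {  # normalize to ascending
    ax <- rev(ax); amp <- rev(amp)
  }
  if (lo < ax[1] || hi > ax[length(ax)]) {
    warning("integration window clipped to the sampled axis")
    lo <- max(lo, ax[1]); hi <- min(hi, ax[length(ax)])
  }
  # trapezoid on the native grid, window edges by linear interpolation
  inside <- ax > lo & ax < hi
  xs <- c(lo, ax[inside], hi)
  ys <- c(stats::approx(ax, amp, lo)$y, amp[inside], stats::approx(ax, amp, hi)$y)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Assemble a z-spectrum from a series of per-offset scans
#'
#' Integrates each scan with [integrate_scan()] and collects the integrals
#' against their irradiation offsets into a z-spectrum, sorted by offset.
#' Intensities are the raw integrals; normalization is a separate step
#' ([normalize_baseline()]).
#'
#' @param scans list of \code{xe_scan1d} with distinct irradiation offsets;
#'   at least 3.
#' @param window_ppm,center,smooth_peak passed to [integrate_scan()].
#' @return an \code{xe_zspectrum}.
#' @export
assemble_zspectrum <- function(scans, window_ppm = 7, center = NULL,
                               smooth_peak = FALSE) {
  ok <- vapply(scans, inherits, logical(1), what = "xe_scan1d")
  if (!all(ok)) stop("scans must be a list of xe_scan1d objects")
  if (length(scans) < 3L) stop("need at least 3 scans to assemble a z-spectrum")
  offs <- vapply(scans, `[[`, numeric(1), "irradiation_offset")
  if (anyDuplicated(offs)) stop("duplicate irradiation offsets in scan set")
  ints <- vapply(scans, integrate_scan, numeric(1),
                 window_ppm = window_ppm, center = center,
                 smooth_peak = smooth_peak)
  zspectrum(offs, ints)
}

#' Normalize a z-spectrum to its off-resonance baseline
#'
#' Divides the intensities by an upper quantile (default 0.9) of the
#' intensity values, a robust estimate of the unsaturated baseline level.
#' The applied scale is recorded in \code{meta$baseline_scale}. The model
#' baseline amplitude absorbs any residual scale during fitting, so this
#' step only conditions the data.
#'
#' @param z an \code{xe_zspectrum}.
#' @param quantile upper quantile used as the baseline estimate, in (0, 1].
#' @return a normalized \code{xe_zspectrum}.
#' @export
normalize_baseline <- function(z, quantile = 0.9) {
  stopifnot(inherits(z, "xe_zspectrum"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1)
    stop("quantile must be in (0, 1]")
  scale <- stats::quantile(z$intensities, quantile, names = FALSE)
  if (scale == 0) stop("baseline quantile is zero; cannot normalize")
  meta <- z$meta
  meta$baseline_scale <- scale
  zspectrum(z$offsets, z$intensities / scale,
            sigma = if (!is.null(z$sigma)) z$sigma / scale else NULL,
            meta = meta)
}

# ---- file I/O --------------------------------------------------------------

#' Read and write z-spectrum CSV files
#'
#' The on-disk format is a CSV with columns \code{offset_ppm},
#' \code{intensity} and optionally \code{sigma}. Acquisition settings can
#' travel in a JSON sidecar (same path with extension \code{.json}) written
#' by \code{write_zspectrum} when an \code{xe_acq} is attached under
#' \code{meta$acquisition}.
#'
#' @param path CSV file path.
#' @param z an \code{xe_zspectrum}.
#' @return \code{read_zspectrum} returns an \code{xe_zspectrum};
#'   \code{write_zspectrum} returns \code{path} invisibly.
#' @export
read_zspectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("offset_ppm", "intensity") %in% names(df)))
    stop("z-spectrum CSV needs columns offset_ppm, intensity")
  meta <- list()
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$acquisition))
      meta$acquisition <- do.call(acquisition_params, as.list(meta$acquisition))
  }
  zspectrum(df$offset_ppm, df$intensity,
            sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
            meta = meta)
}

#' @rdname read_zspectrum
#' @export
write_zspectrum <- function(z, path) {
  stopifnot(inherits(z, "xe_zspectrum"))
  utils::write.csv(as.data.frame(z), path, row.names = FALSE)
  meta <- z$meta
  if (length(meta)) {
    meta <- lapply(meta, function(v) {
      if (inherits(v, "xe_acq")) unclass(v)
      else if (inherits(v, "xe_zspec_params"))
        list(A = v$A, resonances = as.data.frame(v))
      else v
    })
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         null = "null")
  }
  invisible(path)
}

#' Read a scan set from a directory with a manifest
#'
#' Expects a manifest CSV with columns \code{filename} and
#' \code{irradiation_offset_hz} (offset of the saturation pulse in Hz
#' relative to the free-xenon line, positive downfield); each named file is
#' a CSV with columns \code{ppm} and \code{amplitude}.
#'
#' @param dir directory containing the manifest and scan files.
#' @param acq an \code{xe_acq} used to convert manifest offsets to ppm.
#' @param manifest manifest file name within \code{dir}.
#' @return list of \code{xe_scan1d}.
#' @export
read_scan_set <- function(dir, acq = acquisition_params(),
                          manifest = "manifest.csv") {
  mf <- utils::read.csv(file.path(dir, manifest))
  if (!all(c("filename", "irradiation_offset_hz") %in% names(mf)))
    stop("manifest needs columns filename, irradiation_offset_hz")
  lapply(seq_len(nrow(mf)), function(i) {
    df <- utils::read.csv(file.path(dir, mf$filename[i]))
    scan1d(df$ppm, df$amplitude,
           acq$ref_free_xe_ppm + hz_to_ppm(mf$irradiation_offset_hz[i], acq))
  })
}
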