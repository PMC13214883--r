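#' Construct a single Raman spectrum
#'
#' A spectrum is an intensity vector over a strictly increasing wavenumber
#' axis, acquired at a known culture time.
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 2, all finite.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumbers`, all finite.
#' @param time_h Acquisition time in hours since culture start (>= 0).
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities` and `time_h`.
#' @examples
#' s <- raman_spectrum(c(100, 101, 102), c(1, 2, 1.5), time_h = 4)
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, time_h = 0) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L)
    abort_validation("a spectrum needs at least 2 wavenumber channels")
  if (length(wavenumbers) != length(intensities))
    abort_validation("`wavenumbers` and `intensities` must have equal length")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(intensities)))
    abort_validation("spectrum values must all be finite")
  if (any(diff(wavenumbers) <= 0))
    abort_validation("`wavenumbers` must be strictly increasing")
  if (!is.numeric(time_h) || length(time_h) != 1L || !is.finite(time_h) ||
      time_h < 0)
    abort_validation("`time_h` must be a single finite number >= 0")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         time_h = as.numeric(time_h)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum>  t = %.4g h,  %d channels,  %.6g-%.6g cm^-1\n",
    x$time_h, length(x$wavenumbers),
    x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' Construct a time-ordered series of spectra for one batch
#'
#' All spectra in a series share one wavenumber axis; rows of the intensity
#' matrix are individual acquisitions sorted by time.  Input rows may be
#' given in any order; they are re-sorted by `times`.
#'
#' @param times Numeric vector of acquisition times (hours), one per
#'   spectrum.  Duplicated times are rejected.
#' @param wavenumbers Shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, `length(times)` rows by
#'   `length(wavenumbers)` columns.
#' @param batch_id Character label for the batch.
#' @param interval_h Nominal acquisition interval in hours (informational
#'   only; sampling may be irregular).
#' @return An object of class `spectra_series` with elements `times`,
#'   `wavenumbers`, `intensities`, `batch_id`, `interval_h`.
#' @seealso [read_series_csv()], [truncate_range()], [spectrum_at()]
#' @examples
#' wn <- seq(100, 200, by = 10)
#' m <- matrix(rnorm(33), nrow = 3)
#' spectra_series(times = c(0, 1, 2), wavenumbers = wn, intensities = m)
#' @export
spectra_series <- function(times, wavenumbers, intensities,
                           batch_id = "batch", interval_h = NA_real_) {
  times <- as.numeric(times)
  wavenumbers <- as.numeric(wavenumbers)
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  storage.mode(intensities) <- "double"
  if (length(times) < 1L)
    abort_validation("a series needs at least one spectrum")
  if (length(wavenumbers) < 2L)
    abort_validation("a series needs at least 2 wavenumber channels")
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    abort_format("wavenumber axis must be finite and strictly increasing")
  if (nrow(intensities) != length(times) ||
      ncol(intensities) != length(wavenumbers))
    abort_validation(sprintf(
      "intensity matrix is %d x %d but %d times and %d wavenumbers were given",
      nrow(intensities), ncol(intensities),
      length(times), length(wavenumbers)))
  if (any(!is.finite(times)) || any(times < 0))
    abort_validation("times must be finite and >= 0")
  dup <- unique(times[duplicated(times)])
  if (length(dup))
    abort_validation(sprintf(
      "duplicated acquisition times: %s",
      paste(format(dup), collapse = ", ")))
  if (any(!is.finite(intensities)))
    abort_validation("intensities must all be finite")
  ord <- order(times)
  structure(
    list(times = times[ord], wavenumbers = wavenumbers,
         intensities = intensities[ord, , drop = FALSE],
         batch_id = as.character(batch_id)[1],
         interval_h = as.numeric(interval_h)[1]),
    class = "spectra_series"
  )
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf(
    "<spectra_series '%s'>  %d spectra,  t = %.4g-%.4g h,  %d channels (%.6g-%.6g cm^-1)\n",
    x$batch_id, length(x$times), min(x$times), max(x$times),
    length(x$wavenumbers), x$wavenumbers[1],
    x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' @export
length.spectra_series <- function(x) length(x$times)

#' @export
as.matrix.spectra_series <- function(x, ...) {
  m <- x$intensities
  dimnames(m) <- list(format(x$times), format(x$wavenumbers))
  m
}

#' Subset a series by spectrum index
#'
#' @param x A `spectra_series`.
#' @param i Integer or logical index over spectra (rows).
#' @return A `spectra_series` containing the selected spectra.
#' @export
`[.spectra_series` <- function(x, i) {
  spectra_series(x$times[i], x$wavenumbers,
                 x$intensities[i, , drop = FALSE],
                 batch_id = x$batch_id, interval_h = x$interval_h)
}

#' Extract one spectrum from a series
#'
#' @param series A `spectra_series`.
#' @param i Single spectrum index (row).
#' @return A `raman_spectrum`.
#' @export
spectrum_at <- function(series, i) {
  if (length(i) != 1L || i < 1L || i > length(series$times))
    abort_validation("`i` must be a single index into the series")
  raman_spectrum(series$wavenumbers, series$intensities[i, ],
                 time_h = series$times[i])
}

#' Restrict a series to a wavenumber interval
#'
#' Keeps the channels with wavenumber in the closed interval `[lo, hi]`
#' (both endpoints inclusive).  Times and spectrum count are unchanged.
#' The operation is idempotent.
#'
#' @param series A `spectra_series`.
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return A `spectra_series` on the restricted axis.
#' @examples
#' s <- simulate_batch(synthetic_preset("linear-exact"))$series
#' truncate_range(s, 100, 3000)
#' @export
truncate_range <- function(series, lo, hi) {
  stopifnot(inherits(series, "spectra_series"))
  stopifnot_scalar_number(lo, "lo")
  stopifnot_scalar_number(hi, "hi")
  if (lo >= hi) abort_config("`lo` must be < `hi`")
  keep <- series$wavenumbers >= lo & series$wavenumbers <= hi
  if (sum(keep) < 2L)
    abort_validation(sprintf(
      "interval [%g, %g] retains %d channel(s); at least 2 required",
      lo, hi, sum(keep)))
  spectra_series(series$times, series$wavenumbers[keep],
                 series$intensities[, keep, drop = FALSE],
                 batch_id = series$batch_id, interval_h = series$interval_h)
}

#' @export
plot.spectra_series <- function(x, n = 10L, ...) {
  idx <- unique(round(seq(1L, length(x$times), length.out = min(n, length(x$times)))))
  cols <- grDevices::hcl.colors(length(idx), "viridis")
  graphics::matplot(x$wavenumbers, t(x$intensities[idx, , drop = FALSE]),
                    type = "l", lty = 1, col = cols,
                    xlab = expression(paste("wavenumber (", cm^-1, ")")),
                    ylab = "intensity (a.u.)",
                    main = sprintf("batch '%s'", x$batch_id), ...)
  graphics::legend("topright", bty = "n", lty = 1, col = cols,
                   legend = sprintf("%.3g h", x$times[idx]), cex = 0.7)
  invisible(x)
}
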