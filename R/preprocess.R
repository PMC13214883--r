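#' Savitzky-Golay second-derivative detrend configuration
#'
#' Detrending replaces each spectrum by its smoothed second derivative,
#' removing additive and linearly sloping baseline contributions before
#' spectra are compared or modelled.  The derivative is taken with respect
#' to the channel index (the axis is assumed near-uniform), so units are
#' intensity per channel^2.
#'
#' @param window_points Odd filter window length in channels, >= 5.
#'   Default 15.
#' @param poly_order Polynomial order of the local fit, >= 2 and
#'   < `window_points`.  Default 3.
#' @return An object of class `detrend_config`.
#' @export
detrend_config <- function(window_points = 15L, poly_order = 3L) {
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (is.na(window_points) || window_points < 5L || window_points %% 2L == 0L)
    abort_config("`window_points` must be an odd integer >= 5")
  if (is.na(poly_order) || poly_order < 2L || poly_order >= window_points)
    abort_config("`poly_order` must be an integer >= 2 and < window_points")
  structure(list(window_points = window_points, poly_order = poly_order,
                 derivative_order = 2L),
            class = "detrend_config")
}

# Filter matrix cache is cheap to rebuild; keep it simple and rebuild.
sg_filter <- function(cfg) {
  signal::sgolay(p = cfg$poly_order, n = cfg$window_points, m = 2L, ts = 1)
}

d2_rows <- function(m, cfg) {
  if (ncol(m) < cfg$window_points)
    abort_validation(sprintf(
      "spectrum has %d channels; detrending needs >= window_points = %d",
      ncol(m), cfg$window_points))
  f <- sg_filter(cfg)
  t(apply(m, 1L, function(r) signal::sgolayfilt(r, f)))
}

#' Second-derivative detrending of spectra
#'
#' Applies a Savitzky-Golay smoothing second-derivative filter along the
#' wavenumber axis.  Output has the same length as the input (boundary
#' values come from the filter's polynomial edge fits), so detrended
#' spectra stay aligned for cosine comparison.  The filter is linear and
#' annihilates affine baselines.
#'
#' @param x A [raman_spectrum()], a [spectra_series()], or a numeric vector
#'   of intensities.
#' @param cfg A [detrend_config()].
#' @return Same class as `x`, with intensities replaced by the smoothed
#'   second derivative.
#' @examples
#' s <- raman_spectrum(1:20, (1:20)^2, time_h = 0)
#' d2_detrend(s)$intensities  # ~ 2 everywhere
#' @export
d2_detrend <- function(x, cfg = detrend_config()) {
  stopifnot(inherits(cfg, "detrend_config"))
  if (inherits(x, "raman_spectrum")) {
    y <- d2_rows(rbind(x$intensities), cfg)
    return(raman_spectrum(x$wavenumbers, drop(y), time_h = x$time_h))
  }
  if (inherits(x, "spectra_series")) {
    return(spectra_series(x$times, x$wavenumbers,
                          d2_rows(x$intensities, cfg),
                          batch_id = x$batch_id, interval_h = x$interval_h))
  }
  if (is.numeric(x)) return(drop(d2_rows(rbind(as.numeric(x)), cfg)))
  abort_validation("`x` must be a raman_spectrum, spectra_series or numeric vector")
}
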