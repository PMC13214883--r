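#' Cosine similarity between two spectra
#'
#' `Sc(A, B) = (A . B) / (||A|| ||B||)`, the cosine of the angle between
#' the two intensity vectors; invariant to positive rescaling of either
#' argument and bounded in `[-1, 1]`.
#'
#' @param a,b Numeric intensity vectors of equal length, both nonzero.
#' @return A single number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    abort_validation("`a` and `b` must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    abort_undefined("cosine similarity is undefined for a zero vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

as_prediction <- function(predicted) {
  if (inherits(predicted, "anticipation_result")) return(predicted)
  abort_validation("`predicted` must be an anticipation_result")
}

#' Similarity profile of one prediction against a whole batch
#'
#' Computes the cosine similarity between an anticipated spectrum and
#' every actual spectrum of the batch (past and future, window included).
#' `tmin` is the time of the most similar actual spectrum; the signed
#' offset `delta_tmin = tmin - target_time` is 0 for an ideally behaving
#' method.  With the naive baseline the copy matches the anchor spectrum
#' itself, giving `delta_tmin = -horizon` on regularly sampled batches.
#'
#' Ties in similarity are broken towards the candidate closest in time to
#' the target, then towards the earlier time.
#'
#' @param predicted An `anticipation_result` (from [anticipate()] or
#'   [baseline_anticipate()]).
#' @param series The batch the prediction belongs to; axis must match.
#' @param detrend Optional [detrend_config()]; when given, the same
#'   second-derivative transform is applied to the predicted spectrum and
#'   to every actual spectrum before comparison.
#' @return An object of class `similarity_profile`: list with
#'   `target_time_j`, `horizon_i`, `anchor_h`, `times`, `similarities`,
#'   `tmin`, `delta_tmin`, `method`, `batch_id`.
#' @export
similarity_profile <- function(predicted, series, detrend = NULL) {
  predicted <- as_prediction(predicted)
  stopifnot(inherits(series, "spectra_series"))
  if (length(predicted$predicted$wavenumbers) != length(series$wavenumbers) ||
      any(predicted$predicted$wavenumbers != series$wavenumbers))
    abort_validation("prediction and series are on different wavenumber axes")
  p <- predicted$predicted$intensities
  m <- series$intensities
  if (!is.null(detrend)) {
    stopifnot(inherits(detrend, "detrend_config"))
    p <- d2_detrend(p, detrend)
    m <- d2_rows(m, detrend)
  }
  np <- sqrt(sum(p^2))
  nr <- sqrt(rowSums(m^2))
  if (np == 0 || any(nr == 0))
    abort_undefined("cosine similarity is undefined for a zero spectrum")
  sims <- pmin(1, pmax(-1, drop(m %*% p) / (nr * np)))
  j <- predicted$anchor_h + predicted$horizon_h
  ord <- order(-sims, abs(series$times - j), series$times)
  tmin <- series$times[ord[1L]]
  structure(list(target_time_j = j, horizon_i = predicted$horizon_h,
                 anchor_h = predicted$anchor_h,
                 times = series$times, similarities = sims,
                 tmin = tmin, delta_tmin = tmin - j,
                 method = predicted$method, batch_id = series$batch_id),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf(
    "<similarity_profile [%s]>  target %g h (horizon %g h): tmin = %g h, delta_tmin = %+g h\n",
    x$method, x$target_time_j, x$horizon_i, x$tmin, x$delta_tmin))
  invisible(x)
}

#' @export
plot.similarity_profile <- function(x, ...) {
  graphics::plot(x$times, x$similarities, type = "o", pch = 20,
                 xlab = "time of actual spectrum (h)",
                 ylab = "cosine similarity", ...)
  graphics::abline(v = x$target_time_j, lty = 2)
  graphics::points(x$tmin, max(x$similarities), col = 2, pch = 19)
  invisible(x)
}

#' Evaluate a method over all anchors of a batch
#'
#' For every acquisition time `anchor >= config$start_h` with
#' `anchor + horizon <= last time`, forms the prediction (anticipation or
#' baseline) and its [similarity_profile()].
#'
#' @param series A [spectra_series()].
#' @param horizons Numeric vector of anticipation horizons (hours).
#' @param method `"anticipation"` or `"baseline"`.
#' @param config An [anticipation_config()]; `start_h` also gates
#'   baseline anchors.
#' @param detrend Optional [detrend_config()] applied in the comparison.
#' @return A list of `similarity_profile` objects (possibly empty, with a
#'   warning, when no anchor qualifies).
#' @export
evaluate_series <- function(series, horizons,
                            method = c("anticipation", "baseline"),
                            config = anticipation_config(),
                            detrend = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "spectra_series"))
  if (!is.numeric(horizons) || !length(horizons) || any(horizons <= 0))
    abort_config("`horizons` must be positive hours")
  t_end <- max(series$times)
  out <- list()
  for (h in horizons) {
    anchors <- series$times[series$times >= config$start_h &
                              series$times + h <= t_end]
    for (a in anchors) {
      pred <- if (method == "anticipation")
        anticipate(series, a, h, config)
      else baseline_anticipate(series, a, h)
      out[[length(out) + 1L]] <- similarity_profile(pred, series, detrend)
    }
  }
  if (!length(out))
    warning(sprintf(
      "no valid anchors for batch '%s' (start %g h, horizons %s)",
      series$batch_id, config$start_h, paste(horizons, collapse = ", ")))
  out
}

#' Aggregate similarity profiles into a per-horizon summary table
#'
#' Pools `delta_tmin` over all prediction instances (all anchors of all
#' batches) sharing a horizon and reports mean and sample standard
#' deviation (n - 1 denominator; groups of size 1 report sd 0).
#'
#' @param profiles A list of `similarity_profile` objects, possibly
#'   concatenated across several batches.
#' @return A `data.frame` with columns `horizon_h`, `mean_delta_tmin`,
#'   `sd_delta_tmin`, `n`, ordered by horizon.
#' @export
aggregate_horizons <- function(profiles) {
  if (!length(profiles))
    abort_validation("`profiles` is empty; nothing to aggregate")
  h <- vapply(profiles, `[[`, numeric(1), "horizon_i")
  d <- vapply(profiles, `[[`, numeric(1), "delta_tmin")
  hs <- sort(unique(h))
  out <- lapply(hs, function(x) {
    di <- d[h == x]
    data.frame(horizon_h = x, mean_delta_tmin = mean(di),
               sd_delta_tmin = if (length(di) > 1L) stats::sd(di) else 0,
               n = length(di))
  })
  do.call(rbind, out)
}

#' Root-mean-square error between two spectra
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    abort_validation("`a` and `b` must have equal length")
  sqrt(mean((a - b)^2))
}

#' Pearson correlation between two spectra
#'
#' @param a,b Numeric vectors of equal length >= 2, neither constant.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L)
    abort_validation("`a` and `b` must have equal length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_undefined("Pearson correlation is undefined for a constant vector")
  stats::cor(a, b)
}
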