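#' Accumulate the trailing window of spectra at an anchor time
#'
#' Returns the sub-series with acquisition times in the half-open interval
#' `(anchor_h - window_h, anchor_h]`, so each spectrum belongs to exactly
#' one trailing window end.  At 1 h acquisition a 5 h window holds 5
#' spectra; at 30 min it holds 10.
#'
#' @param series A [spectra_series()].
#' @param anchor_h Window end (the "now" of the prediction), hours.
#' @param window_h Window length, hours (> 0).
#' @param min_spectra Minimum spectra required in the window.
#' @return A `spectra_series` restricted to the window.
#' @export
accumulate_window <- function(series, anchor_h, window_h = 5,
                              min_spectra = 3L) {
  stopifnot(inherits(series, "spectra_series"))
  stopifnot_scalar_number(anchor_h, "anchor_h")
  stopifnot_scalar_number(window_h, "window_h", lower = 0, strict_lower = TRUE)
  keep <- series$times > anchor_h - window_h & series$times <= anchor_h
  if (sum(keep) < min_spectra)
    abort_insufficient(sprintf(
      "window (%g, %g] holds %d spectra; %d required",
      anchor_h - window_h, anchor_h, sum(keep), min_spectra))
  series[keep]
}

#' Principal component analysis of a spectral window
#'
#' Mean-centers the window spectra (no channel scaling) and computes the
#' leading components by singular value decomposition.  Scores are the
#' projections of the centered spectra onto the loadings.  For reporting
#' determinism, components are sign-oriented: PC1 so that its score trend
#' against time has non-negative slope, the remaining components so that
#' their largest-magnitude loading element is positive.  Anticipated
#' spectra are provably invariant under either orientation.
#'
#' @param window A `spectra_series` (typically from [accumulate_window()]).
#' @param n_components Number of components to retain (2 or 3).
#' @param flip Optional vector of `+1`/`-1` applied to each retained
#'   component after orientation; a diagnostic hook for verifying
#'   sign-flip invariance of the pipeline.
#' @return An object of class `window_pca`: list with `mean_spectrum`,
#'   `loadings` (channels x components, orthonormal columns),
#'   `explained_variance_ratio`, and `scores` (list with `times`, `pc1`,
#'   `pc2`, optionally `pc3`).
#' @export
fit_window_pca <- function(window, n_components = 2L, flip = NULL) {
  stopifnot(inherits(window, "spectra_series"))
  n_components <- as.integer(n_components)
  if (is.na(n_components) || !(n_components %in% c(2L, 3L)))
    abort_config("`n_components` must be 2 or 3")
  m <- length(window$times)
  if (m < n_components + 1L)
    abort_insufficient(sprintf(
      "window holds %d spectra; PCA with %d components needs >= %d",
      m, n_components, n_components + 1L))
  x <- window$intensities
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  scale0 <- max(abs(x))
  if (max(abs(xc)) <= 1e-12 * (1 + scale0))
    abort_degenerate("all window spectra are identical; PCA is undefined")
  sv <- svd(xc, nu = n_components, nv = n_components)
  total_var <- sum(sv$d^2)
  evr <- sv$d[seq_len(n_components)]^2 / total_var
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # orientation convention
  sgn <- rep(1, n_components)
  s1 <- stats::cov(window$times, scores[, 1L])
  if (s1 < 0) sgn[1L] <- -1
  for (k in seq_len(n_components)[-1L]) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) sgn[k] <- -1
  }
  if (!is.null(flip)) {
    if (length(flip) != n_components || !all(flip %in% c(-1, 1)))
      abort_config("`flip` must be a vector of +1/-1, one per component")
    sgn <- sgn * flip
  }
  loadings <- sweep(loadings, 2L, sgn, `*`)
  scores <- sweep(scores, 2L, sgn, `*`)
  sc <- list(times = window$times, pc1 = scores[, 1L], pc2 = scores[, 2L])
  if (n_components == 3L) sc$pc3 <- scores[, 3L]
  structure(list(mean_spectrum = mu, loadings = loadings,
                 explained_variance_ratio = evr, scores = sc,
                 wavenumbers = window$wavenumbers,
                 window_intensities = x),
            class = "window_pca")
}

#' @export
print.window_pca <- function(x, ...) {
  cat(sprintf(
    "<window_pca>  %d spectra, %d components, explained variance: %s\n",
    length(x$scores$times), ncol(x$loadings),
    paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
          collapse = " + ")))
  invisible(x)
}
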