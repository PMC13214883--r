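#' Fit a stand-in spectrum-to-OD chemometrics model
#'
#' A ridge-regularized linear map from a (optionally second-derivative
#' detrended) spectrum to optical density, standing in for the proprietary
#' machine-learning biomass models used in production settings.  It is
#' deliberately simple and transparent: its only job is to demonstrate
#' that anticipated spectra can be fed, plug-and-play, to any model that
#' consumes spectra.  The penalty is chosen by leave-one-batch-out
#' cross-validation over a fixed log-spaced grid.
#'
#' @param training List of `synthetic_batch` objects (>= 2 batches), or
#'   generally of lists with elements `series` and `truth`.
#' @param detrend Optional [detrend_config()] applied to spectra before
#'   fitting (and, via [predict.od_model()], before prediction).
#' @param lambda_grid Ridge penalties to search.
#' @return An object of class `od_model`: `coefficients` (one per
#'   channel), `intercept`, `lambda`, `detrend`, `wavenumbers`,
#'   `training_batches`, `cv_rmse` (per-lambda leave-one-batch-out RMSE).
#' @export
fit_od_model <- function(training, detrend = NULL,
                         lambda_grid = 10^seq(-6, 4, by = 1)) {
  if (!is.list(training) || length(training) < 2L)
    abort_validation("`training` must hold at least 2 batches")
  for (b in training)
    if (!inherits(b$series, "spectra_series") ||
        !inherits(b$truth, "ground_truth"))
      abort_validation("each training element needs `series` and `truth`")
  wn <- training[[1L]]$series$wavenumbers
  xs <- lapply(training, function(b) {
    if (length(b$series$wavenumbers) != length(wn) ||
        any(b$series$wavenumbers != wn))
      abort_validation("training batches are on different wavenumber axes")
    m <- b$series$intensities
    if (!is.null(detrend)) m <- d2_rows(m, detrend)
    m
  })
  ys <- lapply(training, function(b) b$truth$od)
  batch <- rep(seq_along(training), vapply(xs, nrow, integer(1)))
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  cv <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_along(training), function(k) {
      fit <- ridge_solve(x[batch != k, , drop = FALSE], y[batch != k], lam)
      pred <- drop(x[batch == k, , drop = FALSE] %*% fit$beta) + fit$intercept
      sqrt(mean((pred - y[batch == k])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv)]
  fit <- ridge_solve(x, y, lambda)
  structure(list(coefficients = fit$beta, intercept = fit$intercept,
                 lambda = lambda, detrend = detrend, wavenumbers = wn,
                 training_batches = vapply(training,
                                           function(b) b$series$batch_id,
                                           character(1)),
                 cv_rmse = stats::setNames(cv, format(lambda_grid))),
            class = "od_model")
}

# Exact ridge on centered data via SVD; intercept unpenalized.
ridge_solve <- function(x, y, lambda) {
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  sv <- svd(xc, nu = min(dim(xc)), nv = min(dim(xc)))
  d <- sv$d
  keep <- d > max(d) * 1e-12
  coef_v <- (d[keep] / (d[keep]^2 + lambda)) *
    drop(crossprod(sv$u[, keep, drop = FALSE], y - ym))
  beta <- drop(sv$v[, keep, drop = FALSE] %*% coef_v)
  list(beta = beta, intercept = ym - sum(xm * beta))
}

#' @export
print.od_model <- function(x, ...) {
  cat(sprintf(
    "<od_model>  ridge over %d channels, lambda = %g (LOBO over %d batches)%s\n",
    length(x$coefficients), x$lambda, length(x$training_batches),
    if (!is.null(x$detrend)) ", d2-detrended input" else ""))
  invisible(x)
}

#' Predict OD from spectra
#'
#' @param object An [fit_od_model()] fit.
#' @param newdata A [spectra_series()], `raman_spectrum`, or intensity
#'   matrix on the model's axis.
#' @param ... Unused.
#' @return Numeric vector of predicted OD, one per spectrum.
#' @export
predict.od_model <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "spectra_series")) newdata$intensities
  else if (inherits(newdata, "raman_spectrum")) rbind(newdata$intensities)
  else if (is.matrix(newdata)) newdata
  else rbind(as.numeric(newdata))
  if (ncol(m) != length(object$coefficients))
    abort_validation("`newdata` is not on the model's wavenumber axis")
  if (!is.null(object$detrend)) m <- d2_rows(m, object$detrend)
  drop(m %*% object$coefficients) + object$intercept
}

#' Actual vs predicted vs anticipated-predicted OD trajectories
#'
#' For each acquisition time of the batch, reports the ground-truth OD,
#' the OD predicted by the chemometrics model from the actual spectrum,
#' and - for every horizon - the OD predicted from the spectrum
#' anticipated that many hours in advance (anchor = target - horizon).
#' Per-horizon RMSEs are computed relative to the OD predicted by the
#' chemometrics model from actual spectra, isolating the cost of the
#' anticipation step from the chemometrics model's own error.
#'
#' @param model An [fit_od_model()] fit.
#' @param series The batch's [spectra_series()].
#' @param truth The batch's `ground_truth`.
#' @param horizons Numeric vector of anticipation horizons (hours).
#' @param config An [anticipation_config()].
#' @return An object of class `od_comparison`: `table` (data.frame with
#'   columns `time_h`, `od_actual`, `od_from_actual_spectrum`, and one
#'   `od_from_anticipated_<h>h` per horizon, `NA` where no valid anchor
#'   exists) and `rmse_vs_chemometrics` (named per-horizon vector).
#' @export
od_trajectory_comparison <- function(model, series, truth, horizons,
                                     config = anticipation_config()) {
  stopifnot(inherits(model, "od_model"), inherits(series, "spectra_series"))
  if (length(model$wavenumbers) != length(series$wavenumbers) ||
      any(model$wavenumbers != series$wavenumbers))
    abort_validation("model and series are on different wavenumber axes")
  t_end <- max(series$times)
  keep <- horizons[horizons + config$start_h <= t_end]
  if (length(keep) < length(horizons))
    warning(sprintf("horizon(s) %s exceed the batch span and are omitted",
                    paste(setdiff(horizons, keep), collapse = ", ")))
  tab <- data.frame(time_h = series$times, od_actual = truth$od,
                    od_from_actual_spectrum = predict(model, series))
  rmses <- numeric(0)
  for (h in keep) {
    col <- rep(NA_real_, length(series$times))
    for (i in seq_along(series$times)) {
      anchor <- series$times[i] - h
      if (anchor < config$start_h) next
      ant <- tryCatch(anticipate(series, anchor, h, config),
                      raman_insufficient_data_error = function(e) NULL)
      if (is.null(ant)) next
      col[i] <- predict(model, ant$predicted)
    }
    tab[[sprintf("od_from_anticipated_%gh", h)]] <- col
    ok <- !is.na(col)
    rmses[sprintf("%gh", h)] <-
      sqrt(mean((col[ok] - tab$od_from_actual_spectrum[ok])^2))
  }
  structure(list(table = tab, rmse_vs_chemometrics = rmses),
            class = "od_comparison")
}

#' @export
print.od_comparison <- function(x, ...) {
  cat(sprintf("<od_comparison>  %d time points, horizons: %s\n",
              nrow(x$table),
              paste(names(x$rmse_vs_chemometrics), collapse = ", ")))
  cat("  RMSE of anticipated-OD vs chemometrics-OD:\n")
  for (h in names(x$rmse_vs_chemometrics))
    cat(sprintf("    %s ahead: %.4g\n", h, x$rmse_vs_chemometrics[[h]]))
  invisible(x)
}

#' @export
plot.od_comparison <- function(x, ...) {
  tab <- x$table
  cols <- grDevices::hcl.colors(ncol(tab) - 2L, "Dark 3")
  graphics::matplot(tab$time_h, tab[, -1], type = "l", lty = 1,
                    col = c("black", cols),
                    xlab = "time (h)", ylab = "OD650", ...)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("black", cols), legend = names(tab)[-1],
                   cex = 0.7)
  invisible(x)
}
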