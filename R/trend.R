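trend_kinds <- c("linear", "quadratic", "cubic", "ridge")

#' Fit a score-space trend
#'
#' Least-squares polynomial fit of a score trajectory, used both for the
#' first principal component against time and for the second component
#' against the first.  `"ridge"` is a degree-1 fit with an L2 penalty on
#' the slope (the intercept is not penalized); the predictor is
#' standardized before penalization and the coefficients are mapped back
#' to the original scale, so `ridge_lambda = 0` recovers the ordinary
#' linear fit.
#'
#' @param x Predictor values (time, or PC1 scores).
#' @param y Response values (scores).
#' @param kind One of `"linear"`, `"quadratic"`, `"cubic"`, `"ridge"`.
#' @param ridge_lambda Non-negative penalty, used when `kind = "ridge"`.
#' @return An object of class `trend_fit` with elements `kind`,
#'   `coefficients` (intercept first, ascending powers) and `predictor`
#'   (filled in by the caller; `NA` here).
#' @examples
#' fit_trend(c(0, 1, 2), c(1, 3, 5), "linear")$coefficients  # (1, 2)
#' @export
fit_trend <- function(x, y, kind = c("linear", "quadratic", "cubic", "ridge"),
                      ridge_lambda = 1.0) {
  kind <- match.arg(kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    abort_validation("`x` and `y` must have equal length")
  degree <- switch(kind, linear = 1L, quadratic = 2L, cubic = 3L, ridge = 1L)
  if (length(x) < degree + 1L)
    abort_insufficient(sprintf(
      "%s fit needs >= %d points, got %d", kind, degree + 1L, length(x)))
  if (diff(range(x)) == 0)
    abort_degenerate("all predictor values are equal; trend is undefined")
  if (kind == "ridge") {
    stopifnot_scalar_number(ridge_lambda, "ridge_lambda", lower = 0)
    mx <- mean(x); sx <- stats::sd(x)
    xs <- (x - mx) / sx
    my <- mean(y)
    slope_s <- sum(xs * (y - my)) / (sum(xs^2) + ridge_lambda)
    slope <- slope_s / sx
    coefs <- c(my - slope * mx, slope)
  } else {
    X <- outer(x, 0:degree, `^`)
    coefs <- qr.coef(qr(X), y)
    coefs[is.na(coefs)] <- 0
  }
  structure(list(kind = kind, coefficients = unname(coefs),
                 predictor = NA_character_),
            class = "trend_fit")
}

#' @export
predict.trend_fit <- function(object, newx, ...) {
  drop(outer(as.numeric(newx),
             seq_along(object$coefficients) - 1L, `^`) %*%
         object$coefficients)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit %s vs %s>  coefficients: %s\n",
              x$kind, x$predictor,
              paste(signif(x$coefficients, 6), collapse = ", ")))
  invisible(x)
}
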