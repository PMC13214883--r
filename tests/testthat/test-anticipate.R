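test_that("trend fits recover exact polynomials and validate input", {
  expect_equal(fit_trend(c(0, 1, 2), c(1, 3, 5), "linear")$coefficients,
               c(1, 2), tolerance = 1e-12)
  expect_equal(fit_trend(c(0, 1, 2), c(0, 1, 4), "quadratic")$coefficients,
               c(0, 0, 1), tolerance = 1e-12)
  x <- c(-1, 0, 1, 2); y <- c(-1, 0, 1, 8)
  cubic <- fit_trend(x, y, "cubic")
  # oracle: closed-form normal equations
  X <- outer(x, 0:3, `^`)
  expect_equal(cubic$coefficients, drop(solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)
  expect_error(fit_trend(c(1, 1, 1), c(1, 2, 3), "linear"),
               class = "raman_degenerate_error")
  expect_error(fit_trend(c(0, 1), c(0, 1, 2), "linear"),
               class = "raman_validation_error")
  expect_error(fit_trend(c(0, 1), c(0, 1), "quadratic"),
               class = "raman_insufficient_data_error")
})

test_that("ridge with lambda = 0 equals the ordinary linear fit", {
  set.seed(9)
  x <- rnorm(10); y <- 2 + 3 * x + rnorm(10, 0, 0.1)
  ols <- unname(drop(solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))))
  r0 <- fit_trend(x, y, "ridge", ridge_lambda = 0)
  expect_equal(r0$coefficients, ols, tolerance = 1e-10)
  # a positive penalty shrinks the slope towards zero
  r1 <- fit_trend(x, y, "ridge", ridge_lambda = 10)
  expect_lt(abs(r1$coefficients[2]), abs(ols[2]))
  expect_equal(fit_trend(c(0, 1), c(0, 1), "ridge",
                         ridge_lambda = 0)$coefficients,
               c(0, 1), tolerance = 1e-12)
})

test_that("the trailing window is half-open and acquisition-rate aware", {
  hourly <- exact_linear_series(0:90)
  w <- accumulate_window(hourly, 20, 5)
  expect_equal(w$times, 16:20)          # 5 spectra at 1 h acquisition
  half <- exact_linear_series(seq(0, 90, by = 0.5))
  w2 <- accumulate_window(half, 20, 5)
  expect_equal(w2$times, seq(15.5, 20, by = 0.5))  # 10 spectra at 30 min
  w3 <- accumulate_window(hourly, 2, 5, min_spectra = 3)
  expect_equal(w3$times, 0:2)
  expect_error(accumulate_window(hourly, 1, 5, min_spectra = 3),
               class = "raman_insufficient_data_error")
})

test_that("window PCA satisfies orthonormality and rank-2 identities", {
  b <- toy_basis()
  s <- latent_series(0:6, z1 = c(0, 1, 2, 3.5, 4, 6, 7),
                     z2 = c(1, 0, 2, 1, 3, 2, 4), basis = b)
  p <- fit_window_pca(s)
  L <- p$loadings
  expect_equal(crossprod(L), diag(2), tolerance = 1e-8)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-10)
  # scores reproduce the centered spectra exactly on rank-2 data
  rec <- cbind(p$scores$pc1, p$scores$pc2) %*% t(L)
  ctr <- sweep(s$intensities, 2, p$mean_spectrum)
  expect_lt(max(abs(rec - ctr)) / max(abs(ctr)), 1e-8)
})

test_that("Eckart-Young: residual energy equals unexplained variance", {
  s <- random_series(n_times = 9, n_channels = 40, seed = 21)
  p <- fit_window_pca(s)
  ctr <- sweep(s$intensities, 2, p$mean_spectrum)
  rec <- cbind(p$scores$pc1, p$scores$pc2) %*% t(p$loadings)
  lhs <- sum((ctr - rec)^2) / sum(ctr^2)
  # oracle: full-rank SVD spectrum
  d2 <- svd(ctr)$d^2
  expect_equal(lhs, sum(d2[-(1:2)]) / sum(d2), tolerance = 1e-8)
  expect_equal(lhs, 1 - sum(p$explained_variance_ratio), tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance_ratio) <= 0))
})

test_that("a dominant variation direction shows up as PC1 share > 80%", {
  b <- toy_basis()
  set.seed(2)
  s <- latent_series(0:7, z1 = seq(0, 7) * 2, z2 = rnorm(8, sd = 0.1),
                     basis = b)
  p <- fit_window_pca(s)
  expect_gt(p$explained_variance_ratio[1], 0.80)
})

test_that("degenerate windows are refused", {
  wn <- seq(100, 400, by = 10)
  s <- spectra_series(0:5, wn, matrix(rep(1:31, each = 6), nrow = 6))
  expect_error(fit_window_pca(s), class = "raman_degenerate_error")
  expect_error(anticipate(exact_linear_series(0:30)[1:3], 20, 5,
                          anticipation_config(start_h = 0)),
               class = "raman_insufficient_data_error")
})

test_that("anticipation is exact when the latent dynamics are in the model class", {
  b <- toy_basis()
  s <- exact_linear_series(0:90, basis = b)
  z1 <- function(t) 0.5 + 0.05 * t
  for (anchor in c(20, 40)) {
    fit <- anticipation_fit(s, anchor)
    for (h in c(1, 7, 30)) {
      pred <- predict(fit, h)$predicted$intensities
      truth <- b$mean + z1(anchor + h) * b$v1 +
        (2 + 3 * z1(anchor + h)) * b$v2   # oracle: direct evaluation
      expect_lt(sqrt(sum((pred - truth)^2)) / sqrt(sum(truth^2)), 1e-6)
    }
  }
})

test_that("horizon -> 0+ converges to the trend value at the anchor", {
  set.seed(12)
  s <- latent_series(0:40, z1 = 0.3 * (0:40), z2 = rnorm(41, sd = 0.3),
                     basis = toy_basis())
  fit <- anticipation_fit(s, 25)
  eps_pred <- predict(fit, 1e-9)$predicted$intensities
  hs <- c(0.5, 0.1, 0.01)
  errs <- vapply(hs, function(h)
    max(abs(predict(fit, h)$predicted$intensities - eps_pred)), numeric(1))
  expect_true(all(diff(errs) < 0))
  # it is a regression value, not the raw last observed spectrum
  last_obs <- s$intensities[s$times == 25, ]
  expect_gt(max(abs(eps_pred - last_obs)), 1e-3)
})

test_that("the anticipated spectrum is invariant to PCA sign choices", {
  set.seed(31)
  s <- latent_series(0:30, z1 = 0.2 * (0:30) + rnorm(31, sd = 0.05),
                     z2 = sin((0:30) / 5), basis = toy_basis(),
                     noise_sd = 0.01)
  flips <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  preds <- lapply(flips, function(f)
    predict(anticipation_fit(s, 25, flip = f), 10)$predicted$intensities)
  for (k in 2:4)
    expect_equal(preds[[k]], preds[[1]], tolerance = 1e-10)
})

test_that("anchors before the configured start time are refused", {
  s <- exact_linear_series(0:40)
  expect_error(anticipate(s, 10, 5), class = "raman_config_error")
  expect_error(predict(anticipation_fit(s, 25), -1),
               class = "raman_config_error")
})

test_that("the naive baseline copies the last observed spectrum", {
  s <- exact_linear_series(0:40)
  r <- baseline_anticipate(s, 20, 7)
  expect_identical(r$predicted$intensities, s$intensities[s$times == 20, ])
  expect_equal(r$predicted$time_h, 27)
  # horizon changes only the stamp, never the intensities
  r2 <- baseline_anticipate(s, 20, 30)
  expect_identical(r$predicted$intensities, r2$predicted$intensities)
  # floor semantics off the acquisition grid
  r3 <- baseline_anticipate(s, 19.5, 1)
  expect_identical(r3$predicted$intensities, s$intensities[s$times == 19, ])
  expect_error(baseline_anticipate(s[s$times > 5], 2, 1),
               class = "raman_insufficient_data_error")
})

test_that("model methods expose scores, coefficients and residuals", {
  s <- exact_linear_series(0:40)
  fit <- anticipation_fit(s, 25)
  expect_named(coef(fit), c("pc1", "pc2"))
  expect_length(coef(fit)$pc1, 2L)
  expect_lt(max(abs(residuals(fit))), 1e-10)   # rank-2 truth, zero residual
  expect_equal(dim(fitted(fit)), dim(accumulate_window(s, 25, 5)$intensities))
  out <- summary(fit)
  expect_s3_class(out, "summary.raman_anticipation")
})

test_that("three-component fits back-project all three scores", {
  set.seed(8)
  n <- 40
  q <- qr.Q(qr(matrix(rnorm(n * 3), ncol = 3)))
  t <- 0:30
  m <- outer(0.2 * t, q[, 1]) + outer(sin(t / 4), q[, 2]) +
    outer(cos(t / 3), q[, 3])
  s <- spectra_series(t, seq(100, by = 5, length.out = n), m)
  cfg <- anticipation_config(n_components = 3, start_h = 10)
  r <- anticipate(s, 20, 5, cfg)
  expect_named(r$predicted_scores, c("pc1", "pc2", "pc3"))
  expect_length(r$predicted$intensities, n)
})
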