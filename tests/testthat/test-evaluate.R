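test_that("cosine similarity matches direct evaluation of its formula", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               (4 + 10 + 18) / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 1), c(-1, -1)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 2)),
               class = "raman_undefined_error")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)),
               class = "raman_validation_error")
})

test_that("cosine similarity is bounded and scale invariant", {
  set.seed(17)
  for (i in 1:50) {
    a <- rnorm(20); b <- rnorm(20)
    sc <- cosine_similarity(a, b)
    expect_gte(sc, -1); expect_lte(sc, 1)
    expect_equal(cosine_similarity(3.7 * a, 0.2 * b), sc, tolerance = 1e-12)
  }
})

test_that("baseline similarity profile peaks at the anchor: delta = -horizon", {
  set.seed(23)
  s <- latent_series(0:60, z1 = 0.1 * (0:60), z2 = sqrt(0:60),
                     basis = toy_basis(), noise_sd = 1e-3)
  for (h in c(1, 5, 12)) {
    pred <- baseline_anticipate(s, 30, h)
    prof <- similarity_profile(pred, s)
    # oracle: exhaustive pairwise comparison
    sims <- vapply(seq_along(s$times), function(i)
      cosine_similarity(pred$predicted$intensities, s$intensities[i, ]),
      numeric(1))
    expect_equal(prof$similarities, sims, tolerance = 1e-12)
    expect_equal(prof$tmin, s$times[which.max(sims)])
    expect_equal(prof$tmin, 30)
    expect_equal(prof$delta_tmin, -h)
  }
})

test_that("the ideal method scores delta_tmin = 0 at every horizon", {
  s <- exact_linear_series(0:90)
  for (h in c(1, 5, 10)) {
    prof <- similarity_profile(anticipate(s, 30, h), s)
    expect_equal(prof$delta_tmin, 0)
  }
})

test_that("profiles are invariant to rescaling the prediction", {
  s <- exact_linear_series(0:50)
  pred <- anticipate(s, 25, 5)
  scaled <- pred
  scaled$predicted$intensities <- 2.5 * scaled$predicted$intensities
  p1 <- similarity_profile(pred, s)
  p2 <- similarity_profile(scaled, s)
  expect_equal(p1$similarities, p2$similarities, tolerance = 1e-12)
  expect_identical(p1$tmin, p2$tmin)
})

test_that("profiles honour the d2 preprocessing on both sides", {
  set.seed(4)
  s <- latent_series(0:60, z1 = 0.1 * (0:60), z2 = log1p(0:60),
                     basis = toy_basis(), noise_sd = 1e-3)
  pred <- baseline_anticipate(s, 30, 5)
  prof <- similarity_profile(pred, s, detrend = detrend_config())
  expect_equal(prof$delta_tmin, -5)
  # oracle for one candidate: detrend both sides explicitly
  i <- 10L
  expect_equal(prof$similarities[i],
               cosine_similarity(d2_detrend(pred$predicted$intensities),
                                 d2_detrend(s$intensities[i, ])),
               tolerance = 1e-12)
})

test_that("axis mismatch is rejected", {
  s <- exact_linear_series(0:50)
  pred <- anticipate(s, 25, 5)
  expect_error(similarity_profile(pred, truncate_range(s, 100, 200)),
               class = "raman_validation_error")
})

test_that("evaluate_series enumerates exactly the admissible anchors", {
  s <- exact_linear_series(0:90)
  profs <- evaluate_series(s, 30, "baseline")
  expect_length(profs, 41L)                      # anchors 20..60
  expect_equal(vapply(profs, `[[`, numeric(1), "anchor_h"), 20:60)
  # two horizons: anchor sets shrink with the horizon
  both <- evaluate_series(s, c(10, 30), "baseline")
  h <- vapply(both, `[[`, numeric(1), "horizon_i")
  expect_equal(sum(h == 10), 61L)                # anchors 20..80
  expect_equal(sum(h == 30), 41L)
  expect_warning(out <- evaluate_series(s, 100, "baseline"))
  expect_length(out, 0L)
})

test_that("aggregation pools instances with sample sd and n-1 denominator", {
  mk <- function(h, d) structure(list(horizon_i = h, delta_tmin = d),
                                 class = "similarity_profile")
  tab <- aggregate_horizons(list(mk(5, -5), mk(5, -5), mk(5, -5)))
  expect_equal(tab$mean_delta_tmin, -5)
  expect_equal(tab$sd_delta_tmin, 0)
  expect_equal(tab$n, 3L)
  tab2 <- aggregate_horizons(list(mk(1, -1), mk(1, -2), mk(2, 0.5)))
  expect_equal(tab2$sd_delta_tmin, c(stats::sd(c(-1, -2)), 0))
  expect_equal(tab2$horizon_h, c(1, 2))
  expect_error(aggregate_horizons(list()), class = "raman_validation_error")
})

test_that("baseline on a synthetic cohort reproduces the -i signature", {
  cfg <- small_preset("realistic-yeast", n_batches = 3, seed = 7)
  profs <- list()
  for (b in simulate_cohort(cfg))
    profs <- c(profs, evaluate_series(b$series, c(1, 5, 10), "baseline"))
  tab <- aggregate_horizons(profs)
  expect_equal(tab$mean_delta_tmin, c(-1, -5, -10), tolerance = 1e-10)
  expect_true(all(tab$sd_delta_tmin < 0.02))
})

test_that("rmse and pearson behave on the canonical cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(rmse(c(0, 0, 0, 0), c(1, 1, 1, 1)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "raman_undefined_error")
  expect_error(rmse(1:3, 1:4), class = "raman_validation_error")
})
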