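#' Gaussian band of a pure-component spectrum
#'
#' @param center Band center (cm^-1).
#' @param width Gaussian standard deviation (cm^-1), > 0.
#' @param height Band height (a.u.).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width, height) {
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(width, "width", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(height, "height")
  structure(list(center = center, width = width, height = height),
            class = "peak_spec")
}

#' Latent process trajectory driving a spectral component
#'
#' Three families emulate fermentation dynamics: `"linear"` trends,
#' `"logistic"` biomass-like growth (roughly monotone increase to a
#' plateau), and `"bell"` metabolite-like rise-peak-fall (e.g. ethanol).
#'
#' @param mode `"linear"`, `"logistic"` or `"bell"`.
#' @param intercept,slope Linear mode: value `intercept + slope * t`.
#' @param plateau,rate,midpoint_h Logistic mode:
#'   `plateau / (1 + exp(-rate * (t - midpoint_h)))`; `plateau`, `rate`
#'   > 0.
#' @param amplitude,peak_h,spread_h Bell mode:
#'   `amplitude * exp(-(t - peak_h)^2 / (2 spread_h^2))`; `spread_h` > 0.
#' @return An object of class `latent_config`.
#' @export
latent_config <- function(mode = c("linear", "logistic", "bell"),
                          intercept = 0, slope = 1,
                          plateau = 1, rate = 0.1, midpoint_h = 45,
                          amplitude = 1, peak_h = 45, spread_h = 15) {
  mode <- match.arg(mode)
  params <- switch(mode,
    linear = {
      stopifnot_scalar_number(intercept, "intercept")
      stopifnot_scalar_number(slope, "slope")
      list(intercept = intercept, slope = slope)
    },
    logistic = {
      stopifnot_scalar_number(plateau, "plateau", lower = 0, strict_lower = TRUE)
      stopifnot_scalar_number(rate, "rate", lower = 0, strict_lower = TRUE)
      stopifnot_scalar_number(midpoint_h, "midpoint_h")
      list(plateau = plateau, rate = rate, midpoint_h = midpoint_h)
    },
    bell = {
      stopifnot_scalar_number(amplitude, "amplitude")
      stopifnot_scalar_number(peak_h, "peak_h")
      stopifnot_scalar_number(spread_h, "spread_h", lower = 0,
                              strict_lower = TRUE)
      list(amplitude = amplitude, peak_h = peak_h, spread_h = spread_h)
    })
  structure(list(mode = mode, params = params), class = "latent_config")
}

latent_eval <- function(lc, t) {
  p <- lc$params
  switch(lc$mode,
         linear = p$intercept + p$slope * t,
         logistic = p$plateau / (1 + exp(-p$rate * (t - p$midpoint_h))),
         bell = p$amplitude * exp(-(t - p$peak_h)^2 / (2 * p$spread_h^2)))
}

# Draw n random Gaussian bands with an isolated RNG substream so pure
# spectra are fixed by the seed, shared across all batches of a cohort.
random_peaks <- function(n, lo, hi, seed) {
  with_substream(seed, {
    lapply(seq_len(n), function(i)
      peak_spec(center = stats::runif(1, lo + 50, hi - 50),
                width = stats::runif(1, 8, 60),
                height = stats::runif(1, 0.2, 1)))
  })
}

with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 99991 * as.numeric(i)) %% 2147483647)
}

pure_spectrum <- function(peaks, wn) {
  Reduce(`+`, lapply(peaks, function(p)
    p$height * exp(-(wn - p$center)^2 / (2 * p$width^2))))
}

#' Configuration of the synthetic fermentation cohort
#'
#' Emulates ~90 h fed-batch yeast fermentations monitored in-line: each
#' batch is a sum of pure-component spectra (Gaussian band mixtures on
#' the 100-3425 cm^-1 axis) whose amplitudes follow smooth latent
#' trajectories, plus an additive baseline drift proportional to time and
#' i.i.d. Gaussian channel noise.  The first component is the biomass-like
#' latent; ground-truth optical density is an affine increasing transform
#' of it.
#'
#' @param duration_h Batch duration in hours; default 90.
#' @param interval_h Acquisition interval in hours; default 1 (30-min and
#'   5-min acquisition via 0.5 and 1/12).
#' @param axis_lo,axis_hi,axis_step Wavenumber axis (cm^-1).
#' @param components List of `list(latent = latent_config, peaks =
#'   list of peak_spec)` pairs; default `NULL` means the realistic-yeast
#'   pair built from `seed` (see [synthetic_preset()]).
#' @param baseline_drift Additive drift slope (a.u. per hour, applied to
#'   every channel).
#' @param noise_sd Standard deviation of i.i.d. Gaussian channel noise
#'   (a.u.).
#' @param seed Master seed; every batch uses a distinct substream derived
#'   from it.
#' @param n_batches Cohort size; default 23.
#' @param batch_jitter Relative standard deviation of the multiplicative
#'   perturbation applied to each latent parameter per batch (emulating
#'   different process parameters across lots).
#' @param od_offset,od_gain Affine map from the biomass latent to OD650
#'   (`od_gain` > 0 keeps OD strictly increasing in the latent).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_h = 90, interval_h = 1,
                             axis_lo = 100, axis_hi = 3425, axis_step = 5,
                             components = NULL,
                             baseline_drift = 0, noise_sd = 0,
                             seed = 1L, n_batches = 23L,
                             batch_jitter = 0.05,
                             od_offset = 2, od_gain = 30) {
  stopifnot_scalar_number(duration_h, "duration_h", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(interval_h, "interval_h", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(axis_step, "axis_step", lower = 0, strict_lower = TRUE)
  if (axis_lo >= axis_hi) abort_config("`axis_lo` must be < `axis_hi`")
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(batch_jitter, "batch_jitter", lower = 0)
  stopifnot_scalar_number(od_gain, "od_gain", lower = 0, strict_lower = TRUE)
  n_batches <- as.integer(n_batches)
  if (is.na(n_batches) || n_batches < 1L)
    abort_config("`n_batches` must be >= 1")
  if (is.null(components))
    components <- yeast_components(axis_lo, axis_hi, seed)
  for (cmp in components) {
    if (!inherits(cmp$latent, "latent_config") ||
        !all(vapply(cmp$peaks, inherits, logical(1), "peak_spec")))
      abort_config("each component needs a latent_config and a list of peak_spec")
  }
  structure(list(duration_h = duration_h, interval_h = interval_h,
                 axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
                 components = components, baseline_drift = baseline_drift,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_batches = n_batches, batch_jitter = batch_jitter,
                 od_offset = od_offset, od_gain = od_gain),
            class = "synthetic_config")
}

yeast_components <- function(axis_lo, axis_hi, seed) {
  list(
    list(latent = latent_config("logistic", plateau = 5, rate = 0.08,
                                midpoint_h = 35),
         peaks = random_peaks(8L, axis_lo, axis_hi, substream_seed(seed, 777L))),
    list(latent = latent_config("bell", amplitude = 2, peak_h = 45,
                                spread_h = 15),
         peaks = random_peaks(12L, axis_lo, axis_hi, substream_seed(seed, 778L)))
  )
}

linear_components <- function(axis_lo, axis_hi, seed) {
  # Second latent affine in the first, so the spectral trajectory is a
  # straight line in spectrum space and the anticipation model class
  # contains the truth exactly.
  list(
    list(latent = latent_config("linear", intercept = 1, slope = 0.02),
         peaks = random_peaks(6L, axis_lo, axis_hi, substream_seed(seed, 771L))),
    list(latent = latent_config("linear", intercept = 0.8, slope = 0.012),
         peaks = random_peaks(8L, axis_lo, axis_hi, substream_seed(seed, 772L)))
  )
}

#' Named synthetic presets
#'
#' * `"linear-exact"`: noiseless, drift-free, both latents linear in time
#'   (the second affine in the first) - the anticipation model is exact on
#'   these batches at every horizon, making the preset the workhorse for
#'   ideal-behaviour checks.
#' * `"realistic-yeast"`: logistic biomass-like latent plus bell-shaped
#'   metabolite-like latent, small baseline drift and low channel noise
#'   (about 1% of the within-window signal variation under the default
#'   amplitudes).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synthetic_config()] (e.g.
#'   `interval_h`, `n_batches`, `seed`, `noise_sd`).
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("linear-exact", "realistic-yeast"),
                             ...) {
  name <- match.arg(name)
  over <- list(...)
  axis_lo <- over$axis_lo %||% 100
  axis_hi <- over$axis_hi %||% 3425
  seed <- over$seed %||% 1L
  base <- switch(name,
    "linear-exact" = list(
      components = linear_components(axis_lo, axis_hi, seed),
      noise_sd = 0, baseline_drift = 0, batch_jitter = 0.05),
    "realistic-yeast" = list(
      components = yeast_components(axis_lo, axis_hi, seed),
      noise_sd = 3.6e-4, baseline_drift = 5e-4, batch_jitter = 0.05))
  args <- utils::modifyList(base, over)
  do.call(synthetic_config, args)
}

#' Simulate one fermentation batch
#'
#' Deterministic given `(cfg, batch_index)`: each batch draws its latent
#' parameter jitter and channel noise from a dedicated RNG substream of
#' the master seed.  The spectrum at time t is
#' `sum_c latent_c(t) * pure_c(wavenumber) + drift * t + noise`.
#'
#' @param cfg A [synthetic_config()].
#' @param batch_index Positive integer selecting the batch substream.
#' @return A list of class `synthetic_batch`: `series` (a
#'   [spectra_series()]) and `truth` (class `ground_truth`: `times`,
#'   `latents` matrix, `od`).
#' @examples
#' b <- simulate_batch(synthetic_preset("realistic-yeast"), batch_index = 3)
#' b$series
#' @export
simulate_batch <- function(cfg, batch_index = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  batch_index <- as.integer(batch_index)
  if (is.na(batch_index) || batch_index < 1L)
    abort_config("`batch_index` must be a positive integer")
  times <- seq(0, cfg$duration_h, by = cfg$interval_h)
  wn <- seq(cfg$axis_lo, cfg$axis_hi, by = cfg$axis_step)
  with_substream(substream_seed(cfg$seed, batch_index), {
    comps <- lapply(cfg$components, function(cmp) {
      lat <- cmp$latent
      lat$params <- lapply(lat$params, function(p)
        p * (1 + cfg$batch_jitter * stats::rnorm(1)))
      list(latent = lat, peaks = cmp$peaks)
    })
    z <- vapply(comps, function(cmp) latent_eval(cmp$latent, times),
                numeric(length(times)))
    p <- t(vapply(comps, function(cmp) pure_spectrum(cmp$peaks, wn),
                  numeric(length(wn))))
    intens <- z %*% p + cfg$baseline_drift * times %o% rep(1, length(wn))
    if (cfg$noise_sd > 0)
      intens <- intens + matrix(stats::rnorm(length(intens), 0, cfg$noise_sd),
                                nrow = nrow(intens))
    colnames(z) <- paste0("latent_", seq_len(ncol(z)))
    truth <- structure(
      list(times = times, latents = z,
           od = cfg$od_offset + cfg$od_gain * z[, 1L]),
      class = "ground_truth")
    series <- spectra_series(times, wn, intens,
                             batch_id = sprintf("synthetic-%02d", batch_index),
                             interval_h = cfg$interval_h)
    structure(list(series = series, truth = truth), class = "synthetic_batch")
  })
}

#' Simulate a cohort of batches
#'
#' @param cfg A [synthetic_config()]; `cfg$n_batches` batches are drawn,
#'   each from its own substream (parameter jitter and noise differ per
#'   batch; pure-component spectra are shared).
#' @return List of `synthetic_batch` objects.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lapply(seq_len(cfg$n_batches), function(i) simulate_batch(cfg, i))
}

#' @export
print.synthetic_batch <- function(x, ...) {
  print(x$series)
  cat(sprintf("  ground truth: %d latent component(s), OD %.3g-%.3g\n",
              ncol(x$truth$latents), min(x$truth$od), max(x$truth$od)))
  invisible(x)
}

#' Write a synthetic batch to disk
#'
#' Writes the spectra as a wide CSV (see [write_series_csv()]) and the
#' ground truth as `<stem>_ground_truth.csv` with columns `time_h`,
#' `latent_*`, `od`.
#'
#' @param batch A `synthetic_batch`.
#' @param dir Output directory (created if missing).
#' @param stem File stem; default the batch id.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_synthetic_batch <- function(batch, dir, stem = NULL) {
  stopifnot(inherits(batch, "synthetic_batch"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% batch$series$batch_id
  spath <- file.path(dir, paste0(stem, ".csv"))
  gpath <- file.path(dir, paste0(stem, "_ground_truth.csv"))
  write_series_csv(batch$series, spath)
  gt <- data.table::data.table(time_h = batch$truth$times)
  gt <- cbind(gt, data.table::as.data.table(batch$truth$latents))
  gt$od <- batch$truth$od
  data.table::fwrite(gt, gpath, sep = ",")
  invisible(c(spath, gpath))
}
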