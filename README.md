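# ramanticipate

Predictive monitoring of cell cultures from in-line Raman spectroscopy:
**anticipate future Raman spectra of a running batch from its own early
spectra**, with no historical training data, so that any existing
chemometrics model (spectrum → biomass, metabolite, …) can be turned into
a forecast simply by feeding it the anticipated spectrum.

The intended users are PAT / bioprocess-development scientists who have an
in-line Raman probe in a fermenter and want a day's foresight into the
culture trajectory — e.g. for early go/no-go calls on experimental runs —
without building a mechanistic or machine-learning model first.

## The method

For one batch, let \(s(t) \in \mathbb{R}^n\) be the spectrum acquired at
time \(t\) over \(n\) wavenumber channels (100–3425 cm⁻¹). At an anchor
time \(a\) (default: from 20 h onward):

1. **Accumulate** the spectra in the trailing window \((a - W, a]\),
   default \(W = 5\) h (5 spectra at hourly acquisition, 10 at 30 min).
2. **Project**: fit a mean-centred 2-component PCA to the window; keep
   loadings \(p_1, p_2\) and scores. In practice PC1 carries most of the
   window variance and PC1+PC2 carry ≈ 99 %.
3. **Extrapolate in score space**: fit PC1 scores against time
   (linear by default), predict \(\hat{z}_1(a+h)\) at horizon \(h\); then
   fit PC2 scores against PC1 scores (linear by default) and predict
   \(\hat{z}_2 = g(\hat{z}_1)\).
4. **Back-project**:
   \(\hat{s}(a+h) = \bar{s} + \hat{z}_1 p_1 + \hat{z}_2 p_2\).

The naive baseline for comparison simply re-uses the last observed
spectrum, whatever the horizon.

Quality is judged by cosine similarity
\(S_c(A,B) = A \cdot B / (\lVert A\rVert\,\lVert B\rVert)\)
between a prediction targeted at time \(j\) and *every* actual spectrum of
the batch. If \(t_{\min}(j)\) is the time of the most similar actual
spectrum, the signed offset \(\Delta t_{\min}(j) = t_{\min}(j) - j\) is 0
for an ideal method, while the baseline shows \(\Delta t_{\min} \approx
-h\) (its copy looks like the anchor, \(h\) hours stale). Optionally both
sides are Savitzky–Golay second-derivative detrended before comparison.

Because the real ~90 h fed-batch *S. cerevisiae* dataset behind this
method is proprietary, the package ships a synthetic fermentation
generator (latent logistic biomass + bell-shaped metabolite dynamics
driving Gaussian-band pure spectra, plus drift and noise, with
ground-truth OD650) so the whole pipeline is testable offline.

## Worked example

```r
library(ramanticipate)

batch  <- simulate_batch(synthetic_preset("realistic-yeast", seed = 1))
series <- batch$series
series
#> <spectra_series 'synthetic-01'>  91 spectra,  t = 0-90 h,  666 channels (100-3425 cm^-1)

fit <- anticipation_fit(series, anchor_h = 30)
fit
#> <raman_anticipation 'synthetic-01'>  anchor 30 h, window 5 h (5 spectra)
#>   explained variance: 99.99% + 0.01%
#>   linear fit vs time: (-27, 0.96427)
#>   linear fit vs pc1: (2.2452e-17, 3.9406e-19)

pred <- predict(fit, horizon_h = 10)
prof <- similarity_profile(pred, series)
prof
#> <similarity_profile [anticipation]>  target 40 h (horizon 10 h): tmin = 32 h, delta_tmin = -8 h
```

Reading this: the 5-spectrum window at 30 h is essentially
one-dimensional (PC1 = 99.99 % of variance); the PC1 score grows by
≈ 0.96 per hour. The spectrum predicted for 40 h most resembles the
actual spectrum at 32 h — at this anchor the culture is in its fastest,
most curved growth phase and a linear score extrapolation lags by 8 h.
On data whose latent dynamics really are linear the method is exact at
every horizon:

```r
exact <- simulate_batch(synthetic_preset("linear-exact", seed = 1))
similarity_profile(anticipate(exact$series, 30, 10), exact$series)
#> <similarity_profile [anticipation]>  target 40 h (horizon 10 h): tmin = 40 h, delta_tmin = +0 h
```

The baseline's stale-copy signature \(\Delta t_{\min} = -h\), by
contrast, is structural:

```r
profs <- evaluate_series(series, horizons = c(1, 5, 10), method = "baseline")
aggregate_horizons(profs)
#>   horizon_h mean_delta_tmin sd_delta_tmin  n
#> 1         1              -1             0 70
#> 2         5              -5             0 66
#> 3        10            -10             0 61
```

A ridge spectrum→OD model demonstrates the plug-and-play use
(`fit_od_model()`, `od_trajectory_comparison()`): anticipated spectra are
fed to the model as if they were measurements, and the per-horizon RMSE
against the model's own output on actual spectra isolates the cost of
anticipation.

A subcommand CLI wraps the same functions for shell use
(`simulate`, `anticipate`, `evaluate`, `demo-od`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ramanticipate.R", package = "ramanticipate"))')" \
    simulate --preset realistic-yeast -n 5 --seed 1 --out cohort/
```

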