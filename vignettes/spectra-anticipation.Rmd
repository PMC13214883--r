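---
title: "Anticipating in-line Raman spectra: model, evaluation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipating in-line Raman spectra: model, evaluation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanticipate)
```

## The problem

In-line Raman probes read a fermentation almost continuously, and
chemometrics models turn each spectrum into process quantities such as
biomass. Those models only ever describe the *present*. This package
implements a training-free way to look ahead: extrapolate the batch's own
recent spectra into the future, then let any spectrum-consuming model do
its usual job on the anticipated spectrum. Nothing is learned across
batches; each run is its own calibration set.

## Model and assumptions

At anchor time $a$, the spectra in the trailing window $(a-W, a]$ are
mean-centred and decomposed by SVD; the top two right singular vectors
are the loadings $p_1, p_2$ and the window spectra have scores
$z_1(t), z_2(t)$. Two chained trend fits extrapolate the scores —
$z_1$ against time, then $z_2$ against $z_1$ (the second component is
modelled as a function of the first, not of time) — and the anticipated
spectrum is the inverse projection
$\bar{s} + \hat z_1 p_1 + \hat z_2 p_2$.

The working assumptions, in decreasing order of importance:

* **Local low rank.** Within a $W$-hour window the spectral trajectory is
  close to a 2-plane in channel space. On both synthetic and (reportedly)
  real fermentations PC1 alone captures the bulk of window variance, and
  PC1+PC2 ≈ 99 %.
* **Smooth, near-monotone dynamics.** The extrapolation is polynomial
  (linear by default); it tracks roughly monotone behaviour such as
  biomass accumulation well, and will overshoot around sharp turning
  points (a metabolite peaking, a feed change) until the window has
  refreshed past the event.
* **Stationary measurement conditions.** The probe, axis and acquisition
  settings do not change mid-batch; all spectra share one wavenumber
  axis.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_h` | 5 | h | trailing window length; 5 h holds 5–10 spectra at 1 h/30 min acquisition — enough for a stable 2-component PCA without stale history |
| `start_h` | 20 | h | earliest anchor; the first 20 h (batch phase) are accumulated before predictions begin |
| `n_components` | 2 | — | retained PCs; 3 supported as an extension (PC3 is fitted against PC1, like PC2) |
| `pc1_fit`, `pc2_fit` | linear | — | trend family per projection: linear / quadratic / cubic / ridge. Higher orders fit the window better but extrapolate worse |
| `ridge_lambda` | 1.0 | — | L2 penalty of the "ridge" family (degree-1, slope-only penalty, predictor standardized) |
| `min_window_spectra` | 3 | — | refuse windows with fewer spectra; a line needs 2 points, 3 guards against exact-fit degeneracy |
| `detrend_config()` | 15 / 3 | channels / order | Savitzky–Golay second-derivative window and polynomial order |

Horizons are measured from the anchor (the window end). The baseline
comparator ignores every parameter except the anchor: it re-issues the
last observed spectrum.

## Evaluation framework

A prediction targeted at time $j$ is compared, by cosine similarity, to
*every* actual spectrum of the same batch — including those inside its
own fitting window. $t_{\min}(j)$ is the time of the most similar actual
spectrum and $\Delta t_{\min}(j) = t_{\min}(j) - j$; an ideal method
gives 0, the baseline gives $-h$ by construction on a regular grid with
pairwise-distinct spectra (its copy is bit-identical to the anchor
spectrum, so self-similarity 1 wins). Including window spectra in the
comparison set is what makes this baseline signature exact, and it is
the convention used throughout.

Two wording-level choices deserve a note:

* $t_{\min}$ is the **arg-max of similarity** (equivalently the arg-min
  of the cosine *distance* $1 - S_c$). Ties are broken towards the
  candidate closest in time to the target, then towards the earlier
  time, for determinism.
* Per-horizon tables pool all (batch, anchor) instances directly —
  mean and sample SD ($n-1$; singleton groups report 0) — rather than
  averaging within batches first. With balanced anchors per batch the
  means coincide; pooling keeps $n$ interpretable as "prediction
  instances".

Anchors are every acquisition time from `start_h` onward whose target
$a+h$ still lies inside the batch; anchor spacing therefore follows the
acquisition grid.

`rmse()` and `pearson()` are provided as conventional spectrum-level
comparators alongside the $\Delta t_{\min}$ framework.

## The synthetic generator

Real paired fermentation Raman data of this kind are proprietary, so the
generator stands in for them with *known* latent structure:

$$s(t) = \textstyle\sum_c z_c(t)\, P_c(\nu) + d\,t + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, \sigma^2)\ \text{i.i.d. per channel}$$

with latent families `linear`, `logistic` (biomass-like: roughly
increasing to a plateau) and `bell` (metabolite-like: rise, peak, fall),
and pure-component spectra $P_c$ built as sums of Gaussian bands placed
by the master seed on the 100–3425 cm⁻¹ axis. Ground-truth OD650 is an
affine increasing transform of the biomass latent. Batches of a cohort
share the pure spectra but perturb every latent parameter by a relative
jitter (default 5 %) and draw their own noise, each from a dedicated RNG
substream, so `(config, batch_index)` is fully reproducible.

Defaults emulate the study conditions this method targets: 90 h batches,
hourly acquisition (30-min and 5-min via `interval_h`), 23 lots per
cohort, axis 100–3425 cm⁻¹. The axis step defaults to 5 cm⁻¹ (666
channels) — fine enough that band structure, not the grid, dominates,
while keeping simulation cheap. Two presets are fixed:

* **`linear-exact`** — noiseless, drift-free, both latents linear in time
  (hence the second affine in the first). The spectral trajectory is a
  straight line in channel space, the model class contains the truth,
  and anticipation is exact at every horizon: the ideal-behaviour
  reference, $\Delta t_{\min} \equiv 0$.
* **`realistic-yeast`** — logistic biomass (plateau 5, rate 0.08 h⁻¹,
  midpoint 35 h) plus bell metabolite (amplitude 2, peak 45 h, spread
  15 h), baseline drift $5\times10^{-4}$ a.u./h, channel noise
  $3.6\times10^{-4}$ a.u. That noise level is 1 % of the pooled
  within-window RMS signal variation of the noiseless process under
  these amplitudes — low, instrument-grade noise that keeps windows
  effectively rank-2 (PC1 ≫ 80 %, PC1+PC2 ≥ 99 %).

What the generator deliberately does **not** emulate: cosmic-ray spikes,
detector binning artefacts, heteroscedastic shot noise, spiking
experiments, or control-loop interventions. Passing tests on this
generator therefore show the *mechanics* (projection, extrapolation,
inverse transform, evaluation) are correct and behave as designed; they
do not certify performance on any particular real process. On the
realistic preset the logistic mid-growth phase is strongly curved
relative to a 5 h window, so linear extrapolation lags there (negative
$\Delta t_{\min}$ growing with horizon) — the qualitative degradation
expected of the method, visible here in exaggerated form.

## Numerical choices

* PCA centres on the window mean and never scales channels — channel
  scaling would distort the inverse projection back to spectrum space.
* SVD signs are not identified; for stable logs components are oriented
  so the PC1-vs-time slope is ≥ 0 and each further component's
  largest-magnitude loading element is positive. Predicted spectra are
  invariant under either orientation (verified by forcing all four sign
  combinations through the pipeline via the `flip` hook).
* The window interval is half-open $(a-W, a]$ so each spectrum belongs
  to exactly one trailing window end; windows are refit independently at
  every anchor (no warm start).
* "Regularized" fitting is implemented as ridge on a degree-1 polynomial
  with the intercept unpenalized and the predictor standardized before
  penalization; $\lambda = 0$ reproduces ordinary least squares exactly.
* The second derivative is computed by a Savitzky–Golay
  smoothing-derivative filter (the chemometrics standard) **on the
  channel index**, not on wavenumber units — the axis is treated as
  near-uniform. Same-length output with polynomial edge fits keeps
  detrended spectra axis-aligned for cosine comparison.
* Rank-deficient windows (e.g. the linear-exact preset, whose centred
  window is rank 1) are legitimate: trailing components get zero
  variance and near-zero scores, and the chained fits degrade gracefully
  to the dominant direction. Only an all-identical window is refused.
* The on-disk format writes every number via `%.17g`, so the CSV round
  trip is bit-exact.
* The stand-in OD model is exact ridge regression (SVD closed form, not
  an iterative solver), with the penalty picked by leave-one-batch-out
  CV over a fixed $10^{-6}…10^4$ grid. It is emphatically *not* a
  production biomass model — it exists to demonstrate that anticipated
  spectra can be consumed by any spectrum-to-quantity map.

## Problem sizes

The shipped test-suite and acceptance computations run on deliberately
modest cohorts chosen as the smallest sizes at which every behaviour
under test is stable: 5 batches × 90 h for the baseline signature
(hourly and 30-min), one batch for the exactness check, 20 seeds × 3
batches for explained-variance medians, and 20 seeds × 1 batch for the
horizon-degradation trends. Shape-level unit tests use a coarsened
50 cm⁻¹ axis where channel count is irrelevant.

## Known limitations

* Extrapolation-based by nature: turning points (metabolite peaks,
  process deviations) are tracked only after the window refreshes —
  about one window length of lag at the configured acquisition rate.
* Two components suffice for the processes studied here; a third is
  supported, but the right PC3 trend family is process-dependent and
  deserves its own cross-validated study before routine use.
* No uncertainty bands on anticipated spectra; the similarity framework
  measures *temporal* consistency, not amplitude accuracy — use
  `rmse()`/`pearson()` or the OD demo for that axis.
* Instrument-side corrections (despiking, dark current) are assumed done
  upstream.
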