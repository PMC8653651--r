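---
title: "Quantifying powder adulteration from ATR-FTIR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying powder adulteration from ATR-FTIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirquant)
```

## The problem

Valuable botanical powders are routinely cut with cheaper, visually
indistinguishable species. Mid-infrared attenuated-total-reflectance (ATR-FTIR)
spectroscopy offers a rapid, non-destructive way to quantify such adulteration:
the absorbance spectrum of a two-component powder mixture is, to a good
approximation, a concentration-weighted combination of the pure-component
spectra (Beer–Lambert additivity), so a multivariate calibration can map a
spectrum to the adulterant weight fraction `y` (% w/w).

The catch is that the informative differences between the two species are
small, spread over a 7467-point spectral axis, and buried under scatter,
baseline and noise artifacts. This package implements the complete workflow
a chemometrician applies to that problem:

1. **Pretreatment** — SNV or MSC scatter correction and Savitzky–Golay (SG)
   derivatives, screened as nine candidate chains.
2. **Calibration** — PLS1 regression with leave-one-out (LOO) or k-fold
   cross-validation for choosing the number of latent variables (nLVs).
3. **Wavelength selection** — moving-window PLS (MW-PLS), Monte-Carlo
   uninformative variable elimination (MC-UVE) and interval random frog
   (iRF), which shrink the model to the informative channels.
4. **Evaluation** — RMSEC / RMSECV / RMSEP and R² on an independent test set.

## The synthetic mixture generator

No public spectra exist for this task, so the package ships a generator that
emulates a laboratory mixture study end to end and is itself first-class,
tested code. Its defaults define the study conditions used throughout the
tests:

* **Design** (`default_design()`): 19 adulteration levels, 5–95 % w/w in
  steps of 5, ten replicates per level (190 adulterated samples), plus ten
  pure-target and ten pure-adulterant samples — 210 spectra in all.
* **Axis** (`wavenumber_axis()`): 7467 evenly spaced points over
  400–4000 cm⁻¹, stored descending (spectrometer convention). Axis length is
  a parameter everywhere; a 747-point axis exercises every algorithm at a
  tenth of the cost and is what the examples and the heavier tests use.
* **Components** (`default_profiles()`): both profiles share the
  characteristic band centers of dried plant powders (the broad O–H envelope
  at 3600–3000, alkyl C–H at 2917/2850, C–O stretches at 1732/1604/1371/1318,
  CH₂ at 1417, C–O–C at 1027 and the C–H bend at 808 cm⁻¹) but differ in
  relative amplitudes, plus one adulterant-only shoulder near 1604 cm⁻¹.
  Mixtures therefore look alike by eye while remaining linearly separable.
  The amplitudes are generator configuration, not claims about real plant
  chemistry.
* **Mixing**: a sample at fraction `c` has clean spectrum
  `(c/100)·adulterant + (1 − c/100)·target`.
* **Artifacts** (`noise_model()`): per sample, a multiplicative scatter gain
  `1 + a` with `a ~ N(0, 0.05)`, an additive offset `N(0, 0.01)` AU, a random
  degree-2 polynomial baseline with coefficient sd 0.005 AU, and white noise
  of sd 0.002 AU per channel. These magnitudes are typical of ATR powder
  measurements at 4 cm⁻¹ resolution: scatter variation of a few percent,
  baseline drift of a few mAU, and channel noise well below band amplitudes
  (~0.1–0.9 AU). Replicate scatter within a level comes entirely from this
  model — within-level variability of real powders is otherwise
  uncharacterized, and this is the one place the generator is frankly a
  modelling choice.
* **Reproducibility**: every sample draws from its own substream keyed on
  (level, replicate), so one seed fixes the whole data set bit-exactly and
  growing the design never perturbs existing samples.

What the generator deliberately does **not** emulate: ATR penetration-depth
physics, instrument line-shape functions, water-vapour and CO₂ interference
bands, or nonlinear detector response. Passing tests therefore demonstrate
that the algorithms behave correctly on data obeying the stated model — not
that any particular accuracy will be achieved on real powders.

For testing the selection algorithms the generator also provides
`planted_profiles()`: two components identical except inside one stated
wavenumber window, so all between-class variance is confined to a known
ground-truth band.

## Calibration model

`fit_pls()` implements PLS1 via NIPALS deflation on the mean-centered
predictor matrix and response. No variance scaling is applied: derivative
spectra have meaningful relative magnitudes, and autoscaling would inflate
pure-noise channels. The model exposes the regression vector `b` in centered
coordinates (`ŷ = (x − x̄)·b + ȳ`) and the full coefficient path over
1..nLVs components, which makes cross-validation over all component counts a
single fit per fold. If deflation exhausts the predictive subspace early
(e.g. noise-free two-component mixtures are rank-deficient), the remaining
components are frozen at the last well-defined solution rather than dividing
by vanishing norms.

`cross_validate()` offers LOO and k-fold schemes. k-fold folds are contiguous
blocks of a seeded y-stratified shuffle, so each fold spans the concentration
range; 21-fold mirrors a common screening choice, LOO is the default for
model assessment. The chosen nLVs is the RMSECV argmin with ties broken
toward fewer components (parsimony); no one-standard-error rule is applied.
R² defaults to `1 − SSE/SST` with the squared Pearson correlation available
by argument, and reports state which definition was used — the two differ
for held-out predictions.

## Wavelength selection

**MW-PLS** scans every contiguous window (stride 1) of each requested width
and cross-validates a PLS model inside it; the window with the lowest RMSECV
wins, ties going to the narrower width then the lower start index.

**MC-UVE** draws, per run, 80 % of the calibration samples without
replacement, fits PLS with a fixed nLVs, and records `b`. Channel stability
is `S_j = mean(b_j)/sd(b_j)` over 500 runs. Channels with `sd = 0` get a
signed infinite stability and a flag instead of being silently dropped. Two
cut-offs are provided because the choice is genuinely open for a regression
task: `noise_augmented` appends as many tiny artificial noise channels as
real ones before the runs (S is scale-free, so their amplitude is
irrelevant) and cuts at the largest |S| they attain; `quantile_scan` scans
|S|-quantile cut-offs {0, 50, 60, 70, 80, 90, 95 %} and keeps the survivor
set with the lowest RMSECV. Including the 0 % baseline in the scan
guarantees the chosen set is never worse than no selection.

**iRF** fractionates the axis into one nominal-width-20 interval per channel
(centered sliding windows; edge intervals are truncated and flagged), then
runs a reversible-jump-style search: from a current subset of intervals, a
candidate size is drawn (normal, sd = 0.3 × current size), the candidate is
filled with the best-ranked intervals from the union of the current subset
and random challengers (ranking by mean |b| of a PLS model on the pooled
channels), and is accepted when its 5-fold RMSECV improves — otherwise with
probability `0.1 × (RMSECV_current / RMSECV_candidate)`. Random challengers
enter every iteration, not only when growing, so incumbent intervals must
continually defend their place; without this the search freezes on its
starting subset. After N = 1000 iterations each interval's selection
probability is exactly `n_j / N`; the final channel set is the union of the
top-k intervals (k scanned to the RMSECV minimum, ties to smaller k).
One-interval-per-channel enumeration and these search defaults
(Q₀ = 10, sd factor 0.3, downhill probability 0.1) follow common
random-frog practice; all are arguments.

Inside all selection loops 5-fold CV replaces LOO for tractability; final
reported models may use LOO.

## Pipeline and leakage discipline

`split_train_test()` shuffles within each concentration level (seeded, one
substream per level) and deals alternately, so all 21 levels contribute
evenly: 105 calibration and 105 test samples. Pure-adulterant samples are
split like any level by default; `pure_adulterant = "exclude"` removes them
from both subsets instead.

`run_study()` chains simulate → split → screen → select → fit → evaluate and
is bit-reproducible from one config: every stochastic stage derives a named
substream from the master seed (simulate `s`, split `s+1000`, MC-UVE
`s+2000`, iRF `s+3000`). The MSC reference and every other fitted statistic
come from the calibration set alone; the test set is transformed sample-wise
with the stored reference, and the tests verify that transforming it one
spectrum at a time equals the batch result. Preprocessing screening defaults
to calibration-only data for the same reason; `screen_on = "all"` reproduces
the common (leakier) whole-set screening. Savitzky–Golay edge points are
computed with one-sided fits and flagged rather than dropped; selection can
discard them via `drop_edges`.

## Numerical choices

* SG settings: 15-point window as is conventional for 4 cm⁻¹ MIR spectra;
  polynomial order 3, the smallest supporting both first and second
  derivatives with one setting; derivatives scaled by the (signed) axis
  spacing so outputs are per cm⁻¹ on the descending axis.
* SNV uses the sample (n−1) standard deviation.
* MSC inverts `x ≈ a·ref + b` and refuses |a| < 1e-12.
* NIPALS stops a component when ‖Xᵀy‖ falls below 1e-12 of its initial
  scale.
* All ties (nLVs, windows, interval ranks, top-k) break deterministically
  toward the smaller index, so equal seeds give equal selections.

## Problem sizes used in examples and tests

The documented examples, the heavier tests and the reproduction script run
the full workflow on the 747-point axis with 210 samples — the package's
chosen demonstration scale, at which a complete study takes about a minute —
and the calibration-quality checks additionally run full-spectrum LOO PLS on
the complete 7467-point axis. Nothing in the code depends on these sizes;
they are ordinary arguments.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_points = 747, seed = 1)
report <- run_study(cfg)
report
glance(report)
autoplot(report$final)          # predicted vs actual, both subsets
```

## Known limitations

* The generator's linearity assumption means nonlinear detector or
  penetration-depth effects are untested territory.
* MC-UVE's cut-off for regression has no canonical definition; both provided
  rules are defensible, neither is "the" rule.
* iRF's interval enumeration (one interval per channel) and search
  parameters follow literature convention but other enumerations (tiling,
  stride > 1) are plausible and not implemented.
* With the default generator profiles every spectral region carries some
  signal, so selection methods legitimately keep many channels there; the
  planted-band datasets are the sharp test of selectivity.
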