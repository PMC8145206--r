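---
title: "Predicting dairy-cow bodyweight from milk MIR spectra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dairy-cow bodyweight from milk MIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Live bodyweight (BW) of dairy cows informs feeding, health monitoring,
methane estimation and breeding, but scales are expensive and weighing data
rarely reach Dairy Herd Improvement (DHI) databases. Milk mid-infrared (MIR)
spectra, in contrast, are recorded at every routine milk test. Because milk
composition shifts with the cow's energy balance and body reserves, the
spectrum carries an indirect BW signal that can be combined with days in
milk (DIM), parity and milk yield (MY) in a predictive model.

`mirbw` implements that modeling chain — cleaning, feature selection,
herd-aware validation — as a reusable package, and pairs it with a synthetic
data generator whose ground truth is known exactly, so that every stage can
be tested quantitatively.

## The model

The predictor set is high-dimensional (797 spectral points plus three
covariates) and strongly collinear, the natural territory of partial least
squares regression. The engine (`fit_pls()`) is PLS1 via NIPALS with
X-deflation; weights are unit-norm, scores mutually orthogonal, and the
coefficient vector is recovered as `W (P'W)^{-1} q`, so a fitted model
predicts with a single linear form plus intercept. With as many components
as predictors the fit coincides with ordinary least squares, a property the
test suite checks against a normal-equations oracle at `1e-8`.

Two relevance scores rank features for selection:

* `vip_scores()` — variable importance in the projection; its normalization
  `sum(VIP^2) = p` is asserted for every model the tests fit;
* `beta_scores()` — absolute standardized coefficients. Absolute values are
  used because a strongly negative coefficient is as relevant as a positive
  one; a signed ranking would misplace it.

Ranking ties are broken by ascending feature index so results are
reproducible bit-for-bit.

## Pipeline stages and their tunables

| Stage | Parameter | Default | Why |
|---|---|---|---|
| derivative | gap | 5 points | removes baseline drift; gap differencing is the standard milk-MIR pretreatment |
| GH filter | variance retained | 0.99 | principal components covering 99% of spectral variance |
| GH filter | threshold | 3 | conventional cut for the standardized squared score distance |
| BW ranges | per parity class | (376,705), (449,767), (487,838), (492,875) kg | mean ± SD plausibility windows per class 1, 2, 3, 4+; configuration constants, not re-derived |
| residual clean | SD threshold | 3 | iterate until no residual deviates > 3 SD from the mean residual |
| SBF | alpha | 0.05 | permissive univariate screen; deliberately no multiplicity correction |
| RFE | schedule | step 5 > 255; step 2 in 201–255; step 1 ≤ 200; minimum size 2 | see below |
| retention | tolerances | 0–12 % | 13 candidate models per family |
| validation | share, repeats | 10–30 %, 101 | herd-disjoint partitions |
| PLS | component cap | 10 | parsimony across all stages |
| CV | folds | 10, BW-quartile stratified | type-7 quantile boundaries |

The **first derivative** is the forward difference over the gap,
`d_i = x_{i+gap} - x_i`, anchored at the left wavenumber, shortening the
grid by `gap` points. The convention (forward vs centered, anchor side) is
not fixed by common usage; the forward-difference rule is the simplest one
consistent with "a gap of 5 wavelengths" and is isolated in
`first_derivative()` so an alternative can be swapped in.

The **GH distance** is defined here as the squared standardized
principal-component score distance averaged over the k retained components,
`GH_i = (1/k) sum_a t_{ia}^2 / lambda_a` — the common chemometric "global H".
PCA is computed on the covariance of the (already derivative-transformed,
centered) spectra; a correlation-scaled variant would double-standardize
points that the derivative has already placed on comparable scales. When
every component is retained, GH equals the full-space squared Mahalanobis
distance divided by p, which is how the tests pin the definition to a
brute-force oracle.

The **SBF screen** fits `bw ~ s(x)` per candidate with a penalized cubic
regression spline (basis dimension 10, smoothness by GCV) in `mgcv`, and
tests the no-relationship null with the approximate F-test of the smooth
term. A model-versus-null F-test was considered and rejected on calibration
grounds: in null simulations (500 independent predictors, n = 300) it
retained 10–11% of pure-noise features at the nominal 5% level, while the
smooth-term test stays near 5–7%. Predictors with fewer than four distinct
values fall back to a linear term; constant predictors cannot reject the
null and are dropped with a warning. Parity enters as one ordinal feature
(class 1–4), so the full candidate count is `n_points + 3`.

The **RFE schedule** steps by 5 while more than 255 features remain, by 2
from 255 down to just above 200, and by 1 from 200 down to 2, the starting
size included. Written as a rule on the current size, this reconstruction
is the unique simple scheme that yields 251, 231 and 158 subsets from
starting sizes 379, 280 and 159 — the counts the package treats as the
schedule's defining property (asserted in the acceptance tests). At every
size the retained subset is refit, re-ranked from the new fit, scored by
stratified 10-fold CV, and only then cut further; subsets are therefore
nested along the trace.

Inside the wrapper the **component count** for each subset is chosen by the
same stratified CV over 1..min(10, p, n−1). The alternative — fixing A per
family — would favor large subsets; re-selecting A per subset keeps the
comparison fair and adds no free parameter beyond the global cap.

**Tolerance retention** keeps, for each tolerance t in 0..12, the smallest
subset whose CV RMSE is at most `min RMSE * (1 + t/100)` (ties to the lower
RMSE). The same subset may win several tolerances; entries are kept per
tolerance, so each family always contributes exactly 13 candidates and six
families give 78. De-duplicating instead would change only bookkeeping, not
which models can reach the final; keeping duplicates preserves the
one-model-per-tolerance accounting.

**Herd-independent validation** enumerates every herd subset whose record
share lies in the closed 10–30% band and samples 101 of them uniformly —
without replacement when at least 101 exist, with replacement (and a
warning) otherwise; whether the original design required distinct
partitions is unknowable, and uniform sampling over the feasible lattice is
the least informative choice. The optimal component count is the argmin of
the mean held-out RMSE across repeats, ties to the smaller count
(parsimony). Finalists per family minimize mean herd-independent RMSE with
ties broken by its SD, then CV RMSE, then feature count.

**External validation** refits each finalist on the entire training set at
its chosen component count, freezes the centering/scaling on the training
data, and scores an external herd never touched by any fitting step.
Pairwise Pearson correlations of the external predictions quantify how
interchangeable the selected models are.

## What the synthetic generator emulates

`generate_dataset()` draws multiple herds of unequal size, cows with
repeated test-day records, parities 1–6 (pooled to 1–4+ downstream), and:

* **Milk yield**: a Wood lactation curve `a·DIM^b·exp(-c·DIM)`
  (a = 16, b = 0.20, c = 0.0035), scaled by parity
  (0.85/1/1.06/1.10) plus Gaussian noise (SD 2.5 kg/day) — peak yield
  near 30 kg/day around DIM 60, in the range of routine Holstein records.
* **Bodyweight**: parity-class baselines 560/615/648/665 kg, a herd effect
  (SD 12 kg), a cow effect (SD 20 kg), an early-lactation dip
  `-25·(DIM/50)·exp(1 - DIM/50)` with its nadir near DIM 50, a slow regain
  of 0.12 kg/day, and residual noise (SD 18 kg). Herd means land in the
  550–680 kg band typical of commercial Holstein herds.
* **Spectra**: smooth background peaks (whose amplitudes wobble with MY and
  record-level noise), a per-herd smooth spectral shift, informative-zone
  peaks whose amplitudes are linear in the standardized systematic (non-herd)
  BW signal, smooth autocorrelated noise (white noise convolved with a
  Gaussian kernel of SD 2.5 grid steps) and a small white-noise floor. The
  smooth noise is what gives adjacent spectral points their > 0.9
  correlation, the property that makes many near-equivalent feature subsets
  possible — and testable — downstream.

`signal_to_noise` multiplies the informative peak amplitude per SD of the
latent BW signal, measured in units of the spectral noise SD; at 0 the
spectra are provably uninformative, which the tests use as a negative
control. The ground truth records the informative grid indices, the per-herd
and per-cow effects, injected outlier ids, and the irreducible external
error `sqrt(resid_sd^2 + herd_sd^2)` — herd effects are deliberately not
encoded in the spectra, so they are unpredictable for unseen herds, while
the per-herd spectral shift lets within-herd CV partially absorb them; that
asymmetry reproduces the characteristic gap between stratified-CV and
herd-independent RMSE.

The random stream is partitioned per herd (seed offset by a large prime per
herd index), so enlarging a configuration by more herds leaves existing
herds byte-identical — stable fixtures without stored data files.

What the generator does **not** emulate: FTIR physics, water-absorption
dead regions, instrument-to-instrument standardization error, fatty-acid
chemistry, pregnancy or breed effects, or seasonal/management trends.
Passing tests therefore demonstrate that the machinery is correct and that
the statistical design behaves as intended on data with the assumed
structure — not that any particular accuracy in kg transfers to real milk
recording data.

## Numerical choices and degenerate inputs

* Sample SD (n−1) throughout; scale transforms refuse zero-variance
  features by name (inside CV folds a constant column is tolerated and
  receives zero weight).
* BW plausibility intervals and selection windows are closed intervals.
* NIPALS stops early (with a warning) when a weight vector's norm
  underflows, returning the extractable components.
* Quantiles are type 7 (linear interpolation), matching mainstream
  statistical software.
* Fold assignment shuffles within stratum and deals round-robin, so
  per-stratum fold counts differ by at most one; strata smaller than k
  produce a warning, not an error.
* Identical spectra make the GH PCA degenerate and raise an explicit error.

## Problem sizes used by the tests

The suite exercises the full chain at reduced scale, chosen so the complete
run stays within a couple of minutes on one CPU: grids of 40–200 points
spanning the canonical 925.66–3995.78 cm⁻¹ range, 2–9 herds of 6–20 cows,
10–25 partition repeats, and RFE from up to ~160 starting features. The
combinatorial properties (schedule counts, 13 retained models per family,
78 retained subsets, 78 × 101 evaluations) are asserted exactly; the
statistical properties (filter calibration, feature recovery ≥ 60% of truth,
external RMSE within 15% of the noise floor at high signal-to-noise) are
asserted on fixed seeds at these reduced sizes.

## Known limitations

* PLS1 only; multi-response and sparse/kernel PLS variants are out of scope.
* The wrapper's CV folds are fixed once per dataset; fold-to-fold
  variability of the selection itself is not resimulated.
* The GH filter assumes the spectra fit in memory for a full PCA.
* No multiplicity correction in the univariate screen — by design, as the
  screen is meant to be permissive and the wrapper does the real selection.
* The canonical-grid step implied by the printed endpoints
  (3.8569 cm⁻¹) reproduces published reference wavenumbers only to ~0.01
  cm⁻¹; grids inferred from file headers are validated to that tolerance.
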