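---
title: "Ensembles of Small Models for rare species: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembles of Small Models for rare species: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rarescape)
```

This vignette is the package's own account of the statistical machinery it
implements: the model and its assumptions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The modelling problem

Presence-only records of rare species — here bryophytes with 5 to 29
occurrences in a 389-plot survey — cannot support a conventional SDM fitted
on five or more predictors simultaneously: with so few presences the
model's effective degrees of freedom exceed the information in the data and
validation performance collapses. The Ensemble of Small Models (ESM)
strategy replaces the single large model with all bivariate predictor
combinations, each a model small enough to be estimable from a handful of
presences, and averages them weighted by cross-validated skill, so
uninformative pairs contribute nothing and informative pairs are not
diluted.

Assumptions worth keeping in mind:

* Background (pseudo-absence) points stand in for absences. All inference
  is *relative* ranking of habitat, not absolute occupancy probability.
* One shared background sample is used for every species of a run; the
  presence and background classes are weighted to equal totals (presence
  weight 1, background weight `n_presences / n_background`) so prevalence
  does not distort the fits.
* Occurrence plots are treated as independent observations; the generator
  has a clustering knob but the estimators make no correction for
  clustered sampling.

## 2. Learner families

**Maxent-style learner.** Maxent with linear, quadratic and product
features is equivalent to a penalized logistic regression on that feature
expansion for presence-background data. `maxent_learner()` therefore fits
an L1-penalized logistic model (`glmnet`) on
`(z1, z2, z1^2, z2^2, z1·z2)` of the two predictors, honouring the
balanced case weights. The penalty is selected by 5-fold held-out deviance
(`cv.glmnet`, `lambda.min`) with a seeded fold assignment; a fixed
`regularization` can be supplied instead. The L1 path plays the role of
Maxent's feature regularization: with five presences most features are
shrunk to zero and the model degrades gracefully toward an intercept.

**Random forest.** `rf_learner()` is a probability forest (`ranger`),
500 trees by default, case-weighted, single-threaded and seeded so fits
are reproducible. Its prediction is the mean per-tree presence frequency.

Both learners satisfy a minimal contract (`fit_learner()` /
`predict_prob()`): probabilities in [0, 1], determinism given a seed. A
`constant_learner()` exists solely to make the averaging arithmetic
exactly testable.

## 3. Cross-validation and scoring

The prescription "10-fold cross-validation using 80% of the data to train
and 20% to validate" is internally inconsistent with standard k-fold
(10 folds would hold out 10%). It is implemented as **10 repeated random
stratified 80/20 split-samples** — the split-sample scheme of the ESM
literature — which honours both the count and the fractions. Presences and
background rows are sampled separately (stratification), so every
validation fold contains at least one row of each class by construction;
with 5 presences the split is 4 train / 1 validation.

Each bivariate model's skill is Somers' D = `2·(mean validation AUC) − 1`;
AUC is the rank-based (Mann-Whitney) version with ties counted ½. Models
with `D ≤ 0` are dropped; the rest are weighted proportionally to D
(`ensemble_weights()`). The same splits are shared across all pairs and
both techniques, so ensemble-level out-of-split predictions are simple
weighted sums of the sub-model out-of-split predictions.

Two evaluation choices were open and are fixed as follows:

* **Pooled out-of-split evaluation.** Final-ESM metrics (AUC, TSS,
  sensitivity, threshold) are computed on the predictions pooled over all
  10 validation folds rather than averaged per fold. With as few as one
  held-out presence per fold, per-fold thresholds are meaningless; pooling
  gives a stable ROC and a stable max-SSS threshold. To keep the pooled
  score honest, the ensemble prediction entering the evaluation for split
  *r* weights the sub-models by their skill on the *other* splits only
  (leave-one-split-out weighting); weighting by all-split skill would let
  each fold's own validation rows pick the models that score them, which
  measurably inflates null-species AUC.
* **Cross-technique weights** are the technique ensembles' cross-validated
  Somers' D scores (clamped at zero, normalized); the source prescription
  says only "weighted averaging". If one technique is empty or scores
  non-positively the other takes weight 1; if both are non-empty but
  score zero they are weighted equally; if both are empty the species is
  flagged unmodellable. A small residual selection effect remains at the
  technique-combination level (two techniques weighted by all-split
  scores); the null recovery test bounds it empirically.

Thresholding scans only the observed scores (deterministic; ties go to the
lowest threshold) and predicts presence when `score ≥ threshold`, on the
0–1000 integer scale of the continuous maps. Sensitivity is reported only
for species whose final ESM beats random (`AUC > 0.5`), matching the
reporting convention for such studies.

## 4. Predictor derivation and screening

The index helpers implement the standard formulas — EVI2
`2.5(NIR−RED)/(NIR+2.4·RED+1)`, NDWI1 `(NIR−SWIR1)/(NIR+SWIR1)`, BSI in
normalized-difference form
`((SWIR1+RED)−(NIR+BLUE))/((SWIR1+RED)+(NIR+BLUE))` (the printed source
formula has unbalanced parentheses; the standard normalized form is
adopted), and the PALSAR HV/HH backscatter ratio. TPI subtracts the mean
elevation over an annulus of `15 ≤ d ≤ 20` pixels (Euclidean
centre-to-centre distance, inclusive bounds — the annulus convention of the
common GIS implementation, which does not document its exact distance
rule; centre-to-centre is chosen because it is unambiguous and testable).
Edge cells use the partial annulus; only cells whose annulus lies wholly
outside the raster are masked, so the usable area does not shrink by the
outer radius.

Standardization uses the population (divide-by-n) standard deviation; the
choice is irrelevant downstream (it rescales every layer by the same kind
of factor) but must be fixed for exact tests.

Collinearity screening computes Pearson correlations at the background
points and keeps predictors greedily in an explicit priority order,
dropping any predictor whose |r| with an already-kept one exceeds 0.7. The
priority list encodes the domain-driven choice of which member of a
correlated pair survives — by default NDWI1 over BSI, the
moisture-sensitive index being the ecologically meaningful one for
poikilohydric organisms. An automatic rule cannot reproduce a judgement
call, so the judgement is a parameter.

## 5. The synthetic landscape generator

The generator's defaults *are* the study conditions the pipeline is
designed for: a 30 m grid, five standardized and weakly inter-correlated
predictor layers, a 389-plot network, species with 5–29 occurrences in
guild proportions 33/14/5 (mosses/liverworts/sphagna), and 10,000 shared
background points (tests use smaller background samples; see §7).

* **Fields.** Gaussian random fields are white noise convolved (FFT, on a
  torus) with an isotropic Gaussian kernel of sd `autocorr_range/2` cells,
  giving correlation ≈ `exp(−(d/range)²)` at distance `d`. Default range:
  8 cells — structure comparable to a few hundred metres at 30 m
  resolution, small enough that a 100×100 grid holds many independent
  patches.
* **Correlation control.** Independent fields are centred, orthonormalized
  (QR), then mixed through the Cholesky factor of the target correlation
  matrix, so the empirical correlation matrix equals the target to
  floating point while layers remain smooth. Non-positive-definite targets
  are rejected.
* **Species.** True presence probability is the inverse logit of
  `b0 + a·z1 + b·z2 + c·z1·z2` on the species' two response predictors.
  An exact occurrence count is drawn by weighted sampling of plots without
  replacement, weight proportional to the true probability — prevalence is
  then reproducible, at the cost of a slightly sharper realized niche than
  independent Bernoulli draws would give. The true probability surface is
  retained for recovery tests.
* **Plots.** Uniform sampling of distinct cells by default. The real
  survey's plots came from prior studies with unknown clustering, so a
  clustering knob exists (`plot_clustering`) but no fidelity is claimed
  for it.

What passing tests on this generator do *not* show about real data:
remote-sensing layers are not Gaussian, species respond to more than two
predictors with non-logit link shapes, detection is imperfect, and survey
plots are spatially biased. The generator validates the *machinery*
(estimators, weighting, thresholds, calibration), not ecological realism.

## 6. Richness stacking and Lee's L concordance

Binary maps of modelled species are summed cellwise; per-species nodata
contributes 0 by default (`na_as_absence`), mirroring the treatment of
predictor gaps as predicted absence before richness computation. Guild
maps partition the overall map exactly. Species with empty ensembles are
excluded from stacking with a logged outcome.

For concordance between two richness surfaces, 30 m cells are first
block-averaged by a factor of 10 into 300 m cells (partial edge blocks use
the available cells). The local bivariate Lee's L at cell *i* is

`L_i = n · (Wx̃)_i (Wỹ)_i / sqrt(Σ x̃² · Σ ỹ²)`

with centred variables and row-standardized spatial lags. Decisions the
source prescription leaves open, fixed here and recorded in run metadata:

* **Weights:** queen (8-neighbour) contiguity, row-standardized, no
  self-links; rook available. Masked cells are removed and the remaining
  rows re-standardized.
* **Permutation null:** the Monte Carlo test permutes `y` across unmasked
  cells holding `x` and the weights fixed — the standard conditional
  randomization for bivariate association; permuting both is available.
  Each cell's quantile is the rank of its observed L among observed + 999
  simulated values over 1000, so attainable quantiles are 0.001–1.000;
  quantile > 0.975 ⇒ positive, < 0.025 ⇒ negative.
* **Rescaling:** "centred at 0 and rescaled to −1…1 by dividing by the
  maximum" is ambiguous (max of L, of centred L, or of |centred L|); the
  package divides the centred values by max |centred L|, the only variant
  that guarantees the [−1, 1] range whatever the sign of the extreme.

A caveat the null-calibration test quantifies: the conditional permutation
destroys the autocorrelation of `y`, so for two *smooth but independent*
surfaces the test is anti-conservative (smooth lags look extreme against a
shuffled null). Calibration is therefore asserted on independent white
noise; on smooth nulls the positive rate is higher, which is a property of
this class of permutation test, not of the implementation.

## 7. Problem sizes, tolerances, degenerate inputs

* Exact kernels (AUC, TSS, weights, Lee's L) are tested against
  brute-force oracles at 1e-12; TPI against a double-loop oracle at 1e-9;
  field standardization at 1e-9.
* Simulation tests use sizes chosen to keep the full suite in the tens of
  minutes on one CPU while leaving the contracts sharp: recovery
  replicates run on 100×100 grids with 389 plots and 500 background
  points, forests of 200 trees; the 52-species cohort runs on a 50×50
  grid with 400 background points and 150 trees. The method defaults
  (10,000 background points, 500 trees) remain the package defaults.
* Degenerate inputs fail loudly: zero-variance layers cannot be
  standardized; single-class labels cannot be scored; non-positive-definite
  correlation targets, empty plot networks, inner ≥ outer annulus radii,
  and sub-2×2 grids are rejected. An all-non-positive score set is not an
  error but an *empty, flagged ensemble*; both techniques empty marks the
  species unmodellable, which propagates as `NA` metrics,
  `better_than_random = FALSE`, and exclusion from mapping and stacking.
* Per-species failures inside `run_pipeline()` are caught, recorded in the
  manifest, and do not abort the run. Reruns from an identical
  configuration are byte-identical (every stochastic stage derives its
  seed from the master seed by hashing a stage tag).

## 8. Known limitations

* The raster container is deliberately minimal (matrices + cell size +
  origin, CSV on disk); there is no CRS handling, reprojection or
  resampling — inputs are assumed co-registered, and coordinates pass
  through untouched.
* The Maxent-style learner is the penalized-logistic equivalent of
  Maxent's LQP feature class, not a bit-for-bit reimplementation of the
  reference software.
* Pooled cross-validation metrics can retain a small optimistic bias for
  weak species (cross-technique weights are estimated on all splits); the
  null recovery test bounds the effect (mean null AUC within [0.4, 0.6]).
* Occurrence counts outside [5, 29] are out of contract for the virtual
  species generator, mirroring the modelling design it emulates.
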