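---
title: "Methods: stacked SDM projection of plant functional type shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked SDM projection of plant functional type shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pftshift)
```

## The modelling problem

pftshift implements a stacked species distribution modelling (S-SDM)
workflow for projecting how climate change rearranges plant functional
types (PFTs) across a tropical mountain landscape. Each PFT is represented
by a small set of member tree species (four, in the canonical setup). Per
species, an ensemble of presence/pseudo-absence models estimates occurrence
probability from environmental covariates; per PFT, member probabilities
are summed into a *richness map* and member binary presences into a
*bS-SDM count*, from which presence, dominance, range-shift, fragmentation
and uncertainty summaries follow.

Because continental occurrence and climate archives are not bundled with a
package, the workflow is exercised end-to-end on *virtual* landscapes and
species whose ground truth is known analytically. This turns every stage
into a testable estimator: the true suitability surface, the true niche
optima and the true climate forcing are all available for comparison.

## The synthetic study system

`generate_landscape()` builds spatially autocorrelated predictor layers by
filtered white noise: Gaussian-smoothed standard-normal fields with a
configurable correlation length, rescaled per layer. This is deliberately
simpler than variogram-based geostatistical simulation; the tests need
realistic *structure* (smoothness, gradients, a mountain ridge), not a
calibrated variogram. The default landscape emulates a Central-American-like
domain:

* elevation: non-negative smooth field (range 1200 m) plus a north-south
  ridge (2200 m, Gaussian cross-section), giving peaks near 3400 m;
* temperature: smooth sea-level field (mean 28 degC, sd 0.8 degC) minus a
  lapse of 0.0065 degC/m — the standard environmental lapse rate;
* precipitation: linear latitudinal gradient (900 mm at the dry northern
  edge to 3200 mm at the wet southern edge) plus smooth noise (sd 250 mm);
* seasonality, soil sand/clay/pH: bounded smooth fields;
* slope: centred finite differences of elevation on the spherical grid.

Virtual species follow independent Gaussian responses per environmental
variable (`true_suitability()`), a deliberately restrictive choice: product
Gaussians keep the ground truth analytically invertible, which the
recovery tests require. Niche interactions, skewed responses and biotic
effects are out of scope, so a passing test suite demonstrates estimator
correctness under clean niches — not robustness to the messier response
shapes of real occurrence data. Occurrence records are drawn
cell-proportionally to suitability (optionally times a sampling-bias
surface, whose magnitude is a free parameter — field data give no
calibration for it) and jittered uniformly within the cell so that grid
thinning is genuinely exercised.

Climate scenarios are cellwise affine transforms (`x * factor + offset`)
of the climate layers only; elevation, slope and soils can never be
touched. A "+2 degC, x0.8 precipitation" delta emulates a strong-forcing
scenario without claiming any particular emission pathway.

## Data preparation

* **Thinning** (`thin_to_grid()`): one record per species per cell; the
  first record in input order wins, making thinning deterministic.
* **Minimum records** (`check_min_records()`): species below the
  threshold (default 200 thinned records) are refused unless overridden.
* **Collinearity** (`vif_stepwise()`): the variable with the highest
  variance inflation factor is removed step by step until all VIFs fall
  below 10. VIFs are computed from the inverse correlation matrix; exact
  collinearity falls back to per-variable R-squared with infinite VIFs, and
  among tied maxima the variable later in input order is removed. The
  screening sample pools presences of all species with a uniform background
  sample — the choice of sample is configurable since different samples give
  slightly different VIFs.
* **Clamping** (`clamp_to_range()`): scenario values outside the per-layer
  training range (taken over the whole study-region grid, not only at
  occurrence points) are truncated to the range, and a univariate novelty
  mask records where. Multivariate extrapolation surfaces (MESS/ExDet) are
  deliberately not computed; the masks are per-layer only.

## The ensemble

Four learners stand behind the pluggable learner interface (train on
weighted labelled rows, return a probability predictor):

| learner  | model | pseudo-absences (default) |
|----------|-------|---------------------------|
| GAM      | binomial GAM, thin-plate smooths (mgcv) | 10 000 random |
| SPLINE   | lasso logistic on hinge bases (glmnet)  | 10 000 random |
| MAXENT   | ridge logistic density ratio, linear+quadratic features (glmnet); presence-only | 10 000 random |
| RF       | probability forest (ranger) | equal to presences, disk annulus 2–20 cells |

The hinge-basis lasso plays the adaptive-spline role: hinge features at
interior quantile knots with L1 selection adaptively choose the knots, the
same piecewise-linear model class that adaptive regression splines search
greedily. The ridge density-ratio learner is a maximum-entropy-style
estimator in the exponential-family sense; it is flagged presence-only, so
the calibration statistic is not required of it. Pseudo-absence defaults
follow the common large-background recommendation for regression-type
learners and presence-count-matched geographic contrast for trees; all are
configurable per learner. Pseudo-absences are down-weighted so presence
and absence weight sums match, which keeps predicted probabilities on a
balanced scale; the calibration statistic is therefore evaluated with the
same weights.

Per species and learner, `fit_replicates()` trains replicates on
independent 70/30 splits (default 100; every replicate stores holdout AUC,
Continuous Boyce Index and calibration statistic). Learners whose
replicate-mean metrics all reach 0.7 are retained — the replicate-mean
aggregation (rather than per-replicate filtering) is a deliberate design
choice here. For projection, a uniform random subset of
replicates per learner (default 10) is used, the subsetting rule likewise
being an open choice made here.

Ensembling is strictly unweighted averaging across the retained learner ×
replicate maps. Binarization uses the maxSSS threshold (maximizing
sensitivity + specificity over observed holdout scores, pooled across the
retained replicates per learner; ties go to the smallest threshold, and
comparison is `>=` so cells exactly at threshold are presences). A species
is present in a cell only where at least 3 of the 4 learners agree; a PFT
is present only where at least 2 of its 4 members are present (bS-SDM >= 2),
which buffers the stack against single-species outliers.

## Evaluation metrics

* **AUC**: rank-sum formulation, ties counted one half.
* **CBI** (`boyce_index()`): 101 moving windows of width 0.1 x the
  suitability range; per window the presence fraction P and background
  fraction E; windows with E = 0 dropped; Spearman correlation of P/E
  against the window midpoint. The window count and width are the common
  literature defaults. Note the estimator is only approximately invariant
  under monotone rescaling of the suitabilities: window boundaries live in
  suitability units even though the final correlation is rank-based.
* **Calibration statistic** (`calibration_statistic()`): one minus the
  occupancy-weighted mean absolute gap between mean predicted probability
  and observed frequency over ten equal-width bins — a [0, 1] summary of
  the calibration plot, defined here explicitly since published protocols
  often name such a statistic without its formula. External recalibration
  of projections is deliberately not attempted.

## Downstream analyses

**Dominance.** Per cell, the PFT with the highest richness among those
passing the presence rule; `"None"` where no PFT qualifies. Restricting
the argmax to qualifying PFTs is a documented choice (configurable to an
unrestricted argmax); exact ties are broken by a canonical PFT order and
flagged. Area statistics use exact spherical cell areas (the integral of
the cosine of latitude across each cell) because the default domain spans
20 degrees of latitude; transition flows between two dominance maps are
cross-tabulations whose row/column sums conserve class areas.

**Shifts.** Presence cells become (latitude, altitude) points. The "lower
range boundary" is operationalized as the 5th altitude percentile — a
density-contour reading is not reproducible, a quantile is — and the
upslope shift is the scenario-minus-present difference of that quantile.
For a species whose lower edge is temperature-limited, a uniform warming
of D degC under lapse rate L predicts a shift near D/L; the test suite
recovers 2/0.0065 = 308 m within 25% (as the mean over three simulated
landscapes: the per-landscape statistic carries sampling noise of roughly
60 m from terrain availability). Latitudinal divergence is detected as
kernel-density modes with a topographic-prominence threshold (10% of the
global maximum by default) — a heuristic, deliberately not a formal
multimodality test. Density clouds (2-D Gaussian KDE) are diagnostics
only; no acceptance rests on them.

**Fragmentation.** Within a truncated 3x3 window: Pf = proportion of
observed cells covered; Pff = 2FF/(2FF+FN) over unordered cardinally
adjacent pairs (the standard ordered-pair conditional-frequency estimator
of the probability that a neighbour of a covered cell is covered). Classes:
interior (Pf = 1), patch (Pf < 0.4), transitional (0.4 <= Pf <= 0.6 — the
boundary values, which the strict published inequalities leave
unclassified, are assigned to transitional so the classes are exhaustive),
perforated (Pf > 0.6, Pf > Pff), edge (Pf > 0.6, Pf <= Pff); plus an
area-loss overlay where the PFT's present-day footprint disappears under
the scenario. Window truncation at borders (rather than padding) keeps Pf
a true proportion. The whole classifier is verified against an independent
brute-force implementation on all 512 focal-present 3x3 configurations,
over which exactly five in-PFT classes are attainable.

**Uncertainty.** Per cell and species, a main-effects ANOVA of projected
probabilities over algorithm, replicate, RCP and GCM; fractions are
sequential sums of squares over the total (equal to marginal SS on
balanced designs; on unbalanced inputs the canonical factor order is used
and documented as order-dependent). Interactions are absorbed by the
residual. `rank_factors()` orders factors by median fraction across cells.

## Numerical and problem-size choices

Tolerances: exact worked examples are asserted to machine precision;
cellwise recomputation oracles to 1e-12; VIF oracles to 1e-8; area and
fraction conservation to 1e-9. Degenerate inputs are first-class: all-zero
sampling weights, single-class labels, empty annuli, zero suitability
ranges, constant ANOVA responses and empty presence sets all raise typed
errors or flags rather than NaNs.

Problem sizes in the bundled demo and test suite are chosen so the whole
workflow runs on one CPU in minutes: the demo runs 8 species x 4 learners
x 12 replicates with 1500 background points on a 60x60 grid, projecting 4
replicates per learner; the suitability-recovery experiment uses a 100x100
grid, 500 presences, 3000 background points and 10 replicates. The
full-scale defaults (100 replicates, 10 projected, 10 000 background)
remain the function defaults. The rule-level machinery (fragmentation,
thresholds, ANOVA, flows) is scale-free, so these sizes do not change any
rule being tested, only the Monte Carlo precision of the statistical
recovery checks.

## Reading the demo honestly

The demo's wet-to-dry dominance transition under the drying/warming delta
is asserted as a direction (more area flows wet to dry than the reverse),
never as a magnitude: desk-scale virtual landscapes cannot reproduce
area-change percentages from continental-scale analyses, and the package
does not claim otherwise. Equally, passing recovery tests show the
estimators work under the generator's assumptions (independent Gaussian
niches, unbiased sampling unless a bias surface is supplied, affine
climate forcing); they do not certify performance on real occurrence data
with spatial sampling bias, niche truncation or non-equilibrium ranges.

## Known limitations

* Learner internals are reference implementations behind a plug-in
  interface; no claim is made that they replicate any specific historical
  software's feature classes or tuning.
* Univariate novelty masks only; no multivariate extrapolation surface.
* The prominence-based mode count is bandwidth-sensitive; bandwidths are
  configurable and default to Silverman's rule.
* Unbalanced ANOVA partitions depend on the canonical factor order.
* Rasters are plain geographic grids; no projection/CRS machinery.
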