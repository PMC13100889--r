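---
title: "Methods: multi-resolution SDMs on nested basins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-resolution SDMs on nested basins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package addresses

Species distribution models (SDMs) for freshwater fish are not built on
grid cells but on hydrological catchments, because river life is organised
by drainage: what matters is which basin a fish can reach, and basins nest
inside one another from continental macro-basins down to small
sub-catchments. Products such as HydroBASINS expose this nesting as discrete
resolution levels. The choice of level is a genuine modelling decision — it
fixes the spatial grain of the predictors, the number of modelling units,
and ultimately the area a binary prediction map assigns to a species.

`basinsdm` implements a complete, reproducible workflow for asking how that
choice affects three things: predictive skill (measured by the true skill
statistic, TSS), permutation variable importance, and predicted versus
observed range size. Every stage — synthetic landscape generation, predictor
aggregation, occurrence handling, ensemble fitting, evaluation, range
estimation, cross-resolution comparison — is an exported, tested function,
and a single orchestrator (`run_pipeline()`) runs them end to end from one
master seed.

## Data model

A `basin_hierarchy` stores units keyed by (level, id). Level 4 denotes
macro-basins; finer modelled levels are labelled 8, 9, 10, ... Parent links
connect consecutive *modelled* levels only — intermediate levels that are
not modelled are skipped, since nothing downstream requires them.
Identifiers are opaque strings: nesting and adjacency are the only
operations, so no Pfafstetter arithmetic is implemented. Area (km²) is
authoritative from the attribute table and never recomputed from geometry;
centroids are planar, unitless coordinates used only by the synthetic
covariance kernel. Validation enforces positive areas, child areas summing
to the parent area (relative tolerance 1e-6, matching the precision of a
written CSV), an acyclic same-level downstream graph, and complete parent
chains.

"Adjacent upstream basins" is read as *one-step* upstream neighbours — the
units draining directly into the focal unit — not the full upstream
cascade. This is the minimal reading; because the neighbour operator is a
plain function (`upstream_neighbors()`), a cascade variant can be
substituted for sensitivity analysis without touching the rest of the
pipeline.

## What the generator emulates, and what it does not

The synthetic module replaces the archive downloads (occurrence archive,
basin polygons, climate and flow rasters, dam and land-use layers) with
generators that reproduce the statistical structure the analysis relies on:

- **Nesting.** `sim_hierarchy()` subdivides macro-basins by per-level
  branching factors; areas are log-normal, rescaled so children partition
  the parent exactly; each macro-basin's same-level units form a random
  drainage tree toward one outlet. Macro-basin areas default to a median of
  about 50,000 km², the typical European macro-basin size.
- **Predictors.** Continuous fields (annual mean temperature `bio1`,
  temperature annual range `bio7`, minimum streamflow, roughness) are exact
  multivariate Gaussian draws over basin centroids with exponential
  distance-decay covariance; land-use fractions are logistic transforms of
  such fields; dams are Poisson counts with intensity proportional to an
  exponentiated field times basin area, carried as densities (dams/km²).
  One Cholesky factor is shared across variables, which caps landscapes at
  roughly 10⁴ basins per draw — ample at desk scale.
- **Species.** Occurrence probability follows a product of Gaussian
  (bell-shaped) niche responses, the standard virtual-species construction;
  occupancy is Bernoulli. A species given a temperature-only niche has, by
  construction, zero true dependence on every other predictor — the lever
  used to test importance recovery.
- **Sampling bias.** One spatially autocorrelated effort field is shared by
  all species; detection in an occupied basin has probability
  `1 − exp(−slope · effort)`. Sharing the field across species is exactly
  the structure the target-group pseudoabsence approach assumes. Detection
  only thins presences; false presences are out of scope.

The default scenario fixes the study conditions: 10 macro-basins subdivided
75 × 2 × 2 (750 / 1,500 / 3,000 units at levels 8 / 9 / 10 — halving ratios
close to those of real nested-basin products), ten species with thermal
optima spread over 8–12 °C and 4 °C breadth (peak probability 0.95), and a
detection slope of 0.5 (median detection ≈ 0.39 per occupied basin). These
values were chosen once so that every species has several hundred presences
at the finest level — enough to fit nine learners and clear the inclusion
filter — and so that a meaningful target-group pseudoabsence pool survives
at the coarsest fine level, while detection stays sparse enough
that observed ranges fall well short of true occupancy at fine grain, which
is the regime in which the predicted-minus-observed range gap is expected
to open up toward finer resolutions.

What the generator does **not** emulate: raster-level heterogeneity inside
basins (predictors are constant within a finest-level unit), temporal
dynamics (records carry years only as metadata), dispersal limitation, and
taxonomic or coordinate error beyond a generic flag filter. Passing tests
on synthetic data therefore demonstrate the machinery's correctness and the
qualitative mechanisms — not that any particular real-world effect size
will be reproduced.

## The analysis procedure

Per resolution level, predictors are aggregated up the hierarchy:
area-weighted means for continuous variables and fractions (child basins
proxy equal-resolution cells of unequal extent), total count over total
area for densities — algebraically, again an area-weighted mean. Neighbour
covariates add the unweighted mean over one-step upstream neighbours
(`_up`) or the downstream unit's own value (`_down`); where no neighbour
exists the value is 0, because "no upstream pressure" is a meaningful zero
for pressure-type variables rather than missing data.

Collinearity is screened once per level on the full predictor table:
variables are visited in a priority order and a pair with |Pearson r| ≥ 0.7
drops the lower-priority member; the default priority prefers the
conventional retained set (mean temperature, temperature range, minimum
flow, roughness, land-use fractions, dam densities) over the neighbour
variants. Zero-variance variables are excluded with a distinct reason code,
and every decision is logged to a machine-readable report.

Occurrences are deduplicated to one record per species per finest basin;
coarser presences follow by ancestor mapping, so a record can never change
macro-basin across levels. Species need at least `min_presences` (default
200) presence basins at the coarsest fine level; the list is reused at all
levels. Pseudoabsences come from the target group — basins recorded for
*other* species — restricted to macro-basins occupied by the focal species.
The 10,000-unit cap is applied to the *training* pool after the geographic
split (the cap governs training data; applying it before the split would
let held-out records consume cap budget). The geographically independent
test set is a subset of occupied macro-basins holding 10%–30% of presences
*and* of pseudoabsences, found by randomized-greedy search with restarts:
shuffle, accumulate until the presence fraction enters the range, accept if
both fractions qualify. Species for which no qualifying subset exists
within the restart budget are skipped with a structured error, as a real
run would skip them. Presences weigh 1 and pseudoabsences
`n_presences / n_pseudoabsences` within each role, so the two classes carry
equal total weight.

### The ensemble

Nine members are fitted per species × level behind one contract
(probabilities in [0, 1], per-record weights honoured, deterministic given
a seed): a classification tree (rpart), discriminant analysis on a natural
spline basis (weights enter through weighted class priors, exact here
because weights are constant within class), logistic regression, an
additive logistic model (mgcv), adaptive-spline logistic regression
(natural splines with data-driven knots), a single-hidden-layer neural
network (nnet, standardised inputs), gradient-boosted trees (xgboost), a
probability random forest (ranger), and a maximum-entropy-style member
realised as ridge-penalised logistic regression on linear plus quadratic
features fitted to presences against the target-group background. Knots
that would collapse onto a boundary (zero-inflated variables such as dam
density) trigger a fallback to a linear term; the additive model switches
to the discretised fitter above 500 rows for speed. Hyperparameters default
to the registry values recorded in the run manifest.

Each member is scored by stratified five-fold cross-validation (each fold
holds out 1/k of each class within one record), taking the maximal TSS on
the held-out fold and averaging. Ensemble weights are proportional to
cross-validated TSS clamped at zero — a member below random skill should
not pull the ensemble — renormalised to one; if every member is at or below
zero the ensemble falls back to equal weights and is flagged
uninformative. The combination rule is the weighted *mean* of member
probabilities (the simplest reading of TSS-weighting; mean versus median is
exposed by the registry design should anyone want the alternative), so the
ensemble prediction is always a convex combination of member predictions.
Members are refitted on all training data with the cross-validation weights
kept — the weights are the only weighting evidence available — and the
binarisation threshold is set by maximising TSS on the training
predictions of that refit ensemble.

### Evaluation and ranges

`max_tss_threshold()` scans the sorted unique predicted values plus 0
and 1 — an exact optimisation, with an optional fixed-grid mode for
platform-style scanning — under the rule `poo ≥ threshold ⇒ presence`, and
breaks ties toward the *smallest* threshold, i.e. toward larger predicted
ranges; the tie-break is a package choice (the alternative shrinks ranges)
and directly affects range results. Independent-test TSS re-optimises the
threshold on the test set by default, with a reuse-the-training-threshold
mode available; both are reported per model so the choice is transparent.

Permutation importance shuffles one variable at a time (default 10
permutations, seeded per species × level), predicts, and takes
`1 − mean Pearson r` against the unpermuted predictions; a constant
prediction vector contributes r = 1 (no detectable influence), and
variables outside the retained set score exactly 0.

Predicted ranges are constrained to macro-basins with at least one focal
occurrence; basins at or above the threshold are summed by area. Observed
ranges sum the areas of basins holding at least one *cleaned* record (all
records, not training records only — the observed range describes the data,
not the split). The headline statistic is
`(predicted − observed) / observed`, unclamped. Across-species summaries
use medians and 95% ranges with linear-interpolation quantiles.

Cross-resolution comparison applies Levene's test (median-centred) to the
per-level TSS distributions, then a one-way repeated-measures ANOVA with
species as the repeated unit. When the level effect is numerically zero the
F ratio is 0/0; the boundary p-value of 1 is reported explicitly.

## Seeds and numerical choices

All randomness flows from one master seed through `derive_seed()`, a
deterministic string-tagged hash, so any stage can be re-run in isolation
bit for bit; no stage consumes global RNG state (`with_seed()` restores
the caller's `.Random.seed`). Covariance matrices get a 1e-8 diagonal
jitter before Cholesky. Conservation identities are tested at 1e-9
relative tolerance (sums of squares, aggregation totals) and 1e-6 for
CSV-borne areas. Degenerate inputs have defined behaviour throughout:
single-class data, empty pseudoabsence pools, unattainable holdouts and
broken references all raise structured, subclassed errors that the
pipeline's per-species isolation catches and tabulates.

The reference problem sizes — 3,000 finest-level basins, ten species, three
modelled levels, five folds, ten permutations — are the package's default
study conditions; the demo scenario (five macro-basins, eight species,
levels of 20/60/120 units) exists for quick smoke runs, where the smallest
level routinely and legitimately fails the holdout search.

## Known limitations

- The maximum-entropy member is a regularised logistic approximation, not
  the full feature-class machinery of dedicated MaxEnt software.
- The effort-field model of sampling bias is a stand-in: no quantitative
  description of real archive bias is implied, and its parameters are
  scenario choices, not estimates.
- One-step upstream adjacency is an interpretation; the full cascade is not
  implemented.
- The repeated-measures ANOVA assumes sphericity; no correction is applied
  because the package reports the test as a descriptive comparison, not as
  confirmatory inference.
- Synthetic landscapes cap at ~10⁴ basins per covariance draw; larger
  landscapes would need a sparse or spectral field simulator.
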