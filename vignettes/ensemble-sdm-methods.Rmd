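---
title: "Methods: ensemble species distribution modelling with ensembleSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble species distribution modelling with ensembleSDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleSDM)
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the parameters that matter, and the
choices we made where the methodology is genuinely open.

## The modelling problem

A species distribution model (SDM) relates recorded occurrences of a
species to environmental conditions and predicts, for every map cell, a
probability-like suitability score. The pipeline here targets the common
presence-background design: presences are observed records; absences are
not observed but simulated as *pseudo-absence* background points. Suitability
maps for current and future (scenario-shifted) climate are then classified
into discrete classes and differenced to quantify projected range change.

No single learner is reliably best across species and landscapes, so five
algorithms of different families are fitted and combined by weighted
averaging — the ensemble forecasting approach that has become standard in
this field.

## Data model and formats

All map algebra runs on `raster_grid` objects: north-up, square-cell
lon/lat (WGS84) grids with `NA` as the nodata mask. Files are read and
written as ESRI ASCII grids, a plain-text single-band geospatial format
with a full georeference and a declared nodata sentinel (−9999). The
format's one restriction is square cells, which matches the
equal-arc-minute distribution grids of bioclimatic data. Co-registration is
a *precondition* everywhere: layers that disagree in shape, georeference or
CRS are a hard error, never silently resampled — silent resampling is a
classic source of corrupted SDM results.

Cell membership uses half-open intervals, `[west, east)` in longitude and
`(south, north]` in latitude, so points on shared cell edges are assigned
unambiguously; the convention is exercised against a brute-force
bounding-box scan in the tests.

## Occurrence preparation

Presences are thinned to at most one record per analysis cell (first by
input order), and records on nodata cells or outside the extent are
dropped with logged counts. Pseudo-absences are drawn uniformly over valid
cell centres, *without replacement*, rejecting any candidate within a
minimum great-circle distance of any presence (default 5 km, haversine on
a sphere of radius 6371.0088 km). Defaults follow the presence-background
design the pipeline reproduces: 2000 background points against roughly
700 presences at full scale. Rejection sampling with a `max_attempts`
guard is exact and simple at these scales; we deliberately do not
pre-compute exclusion buffers. Cell-centre placement (rather than
continuous coordinates) reflects that predictors are extracted per cell, so
sub-cell placement adds no information. Sampling over the full stack extent
is the default; masking to a sub-extent is the caller's responsibility via
the nodata mask.

## Collinearity screening

Bioclimatic variables are notoriously collinear. The screen has two
deterministic stages:

1. **Pairwise Pearson**: while any pair of predictors has |r| > 0.7, drop
   one member of the worst pair — the one with the larger mean absolute
   correlation against the remaining predictors, ties broken towards the
   later column. Zero-variance columns (undefined r) are retained and
   flagged.
2. **Stepwise VIF** (`vifstep`): compute VIF_j = 1/(1 − R²_j) from
   regressing predictor j, with intercept, on all others; repeatedly drop
   the largest VIF while it exceeds 10. Perfect collinearity is reported at
   a finite cap (10¹²) rather than crashing.

The order (correlation first, then VIF) mirrors the usual two-stage
narrative of SDM methods sections; both thresholds are arguments, never
hidden. The post-screen guarantee — no retained pair above the r threshold,
no retained VIF above the VIF threshold — is verified in the tests by
independent recomputation (normal-equations least squares), not by trusting
the implementation under test. Which member of a near-duplicate pair
survives is a heuristic choice and is logged so users can audit it; for
analysis purposes a 0.98-correlated copy is an essentially equivalent
carrier of the same signal.

## The five learners

Each algorithm is wrapped behind one contract: `fit_model()` returns a
probabilistic classifier, `predict_proba()` scores feature rows that must
match the training columns exactly and in order (no silent reordering).
Training is deterministic given the spec's seed. Backends: random forest
(`randomForest`, 500 trees), boosted trees (`xgboost`, 200 rounds, depth 3,
learning rate 0.1, single thread for determinism), single-hidden-layer
perceptron (`nnet`, hidden size = number of features, weight decay 0.01,
standardised inputs), RBF support vector machine (`e1071`, probability
outputs), and an in-package adaptive regression spline learner of the MARS
family: forward selection of reflected hinge pairs max(x−t, 0)/max(t−x, 0)
by the residual variance they explain over quantile knots, backward pruning
by generalised cross-validation (penalty 3), and a final binomial GLM refit
of the selected basis so outputs are calibrated probabilities. The forward
pass selects against the current residual (a forward-stagewise
approximation to full re-fitting per candidate), which keeps the fit fast
and fully deterministic.

Hyperparameters are fixed, recorded defaults rather than tuned values:
reproducibility is prioritised over squeezing out skill, and every value
can be overridden per algorithm. Class imbalance between presences and
pseudo-absences is left as-is (no reweighting), matching common practice in
this design.

## Evaluation

AUC is computed by the exact rank (Mann–Whitney) formulation with midrank
ties; the all-pairs count (wins + ½ ties)/(n₁·n₀) is the test oracle. TSS
is maximised over the finite threshold grid of observed scores plus {0, 1}
— the maximum of a step function is attained at an observed score — with a
`score ≥ t` positivity rule and the smallest maximising threshold reported.

The resampling harness is `runs` × stratified k-fold cross-validation
(default 10 × 4-fold): per run a fresh seeded partition, every row scored
exactly once by a model not trained on it, per-fold class counts within one
of proportional. A single stratified 70/30 split mode exists as an
alternative scheme flag, since both designs appear in the applied
literature; the repeated k-fold is the default. Per-replicate metrics pool
each run's held-out folds; the performance table reports per-algorithm
means over replicates plus an unweighted grand mean across algorithms,
with replicate counts shown alongside. Skill grades (fail/poor/fair/good/
excellent) use half-open bands with a closed top (AUC edges 0.6/0.7/0.8/
0.9; TSS edges 0.2/0.4/0.6/0.8) and the applied banding is always emitted
with the result, because the banding convention varies across the
literature.

## Ensemble and variable importance

Member weights are w_i ∝ max(metric_i − floor, 0), normalised; the floor is
0.5 for AUC (a random ranker has AUC 0.5) and 0 for TSS, so no-skill
members get zero weight. If every member is at or below the floor the
ensemble falls back to uniform weights with a warning rather than failing.
Predictions are convex combinations, so the ensemble output is bounded by
the member envelope per row — an invariant the tests assert. Raster
prediction is block-wise over cells to bound memory and is verified to be
independent of block size.

Variable importance is the permutation "correlation metric": for predictor
j, importance = 100 × mean over repeats of (1 − Pearson r between ensemble
predictions on the intact table and on a copy with column j permuted),
floored at zero. Contributions are *not* constrained to sum to 100 — each
is a standalone statistic. Importance is computed on the ensemble output
(not per member and averaged), which is the quantity the final maps are
made from; repeats default to 5 with derived seeds.

## Suitability classes and change accounting

Suitability maps are classified with half-open bins [lower, upper), top bin
closed at 1 — a value on a shared edge (e.g. 0.25) belongs to the upper
bin. The published class bounds ("0–0.25", "0.25–0.5", ...) overlap at the
edges, so *some* convention is mandatory; ours is stamped into every
report. Area percentages are simple cell fractions of the valid area by
default, with an optional cosine-latitude weighting mode for geographic
grids (off by default and flagged in output, since fixed-resolution
cell-count percentages are what desktop GIS workflows report).

Change accounting binarises the class maps (suitable ⇔ class ≥ "low",
consistent with reporting "total suitable habitat" as the low-to-high
range; configurable) and overlays them into four categories: stable
unsuitable, gain, stable suitable, loss. The change rate per class is
AC = (A_f − A_c)/A_c × 100, computed at full precision and undefined (a
hard error) when A_c = 0. The overlap area A_cf (suitable in both periods)
is reported alongside via the stable-suitable count but plays no role in
AC. Overlay identities — gain + stable suitable = future suitable count,
loss + stable suitable = current suitable count, categories partition the
valid cells — are asserted exhaustively in the tests.

## The synthetic world

The simulator generates the statistical world the analysis assumes, so
every stage is testable offline:

- **Fields**: seeded white noise smoothed by a Gaussian operator with
  reflecting edges (length scale `autocorr_length` cells, default 8),
  standardised to mean 0 / sd 1. This is the simplest generator with a
  controllable spatial correlation scale.
- **Collinearity on purpose**: each collinear copy is its parent plus a 0.2
  noise admixture (r ≈ 0.98), which the screen must catch.
- **Truth**: a logistic niche p = plogis(β₀ + Σβⱼxⱼ + Σγⱼxⱼ²). The default
  species (β₀ = −5, β = (5, −4) on the two signal layers, γ = −1 on the
  first) occupies roughly 15 % of the landscape. The coefficients were
  fixed once, by design, to give a low-prevalence species with a sharply
  structured niche — the regime in which habitat-suitability studies
  operate and report high discrimination; the Bayes-optimal AUC of this
  design (scoring by the true suitability itself) is about 0.89, so
  fitted-model skill near 0.9 is attainable but not guaranteed.
- **Sampling**: presences are drawn without replacement with probability
  proportional to truth (one record per cell, mirroring the dedup stage);
  the default study size is 400 presences and 800 pseudo-absences on a
  100 × 100 grid of 5-arc-minute cells — chosen to keep the full pipeline,
  including 10 × 4-fold cross-validation of all five learners, around half
  a minute on a single core while leaving headroom above the recovery
  thresholds the tests assert.
- **Scenarios**: additive mean shifts on named layers — the minimal
  mechanism that yields a nontrivial, analytically known change map
  (variance and correlation structure unchanged).

What the simulator does *not* emulate: sampling bias, dispersal limitation,
observation error in coordinates, non-stationary niche responses, and the
shared-trend spatial autocorrelation between predictors and residual that
real climate surfaces carry. Passing the recovery tests therefore shows the
pipeline's machinery is correct and self-consistent — not that any
particular real-world dataset meets the assumptions.

## Numerical and degenerate-input choices

- Determinism throughout: every stochastic stage derives its seed from one
  master seed; reruns reproduce all numeric outputs bit-for-bit (asserted).
- VIF under perfect collinearity is capped at 10¹² and flagged, never Inf.
- Zero-variance predictors: retained by the correlation screen (r treated
  as 0) and logged; constant ensemble predictions make permutation
  importance undefined and are reported as 0 with a warning.
- Suitability values marginally outside [0, 1] (≤ 10⁻⁸) are clamped with a
  warning; larger excursions are errors.
- Ties: the worst correlated pair and the largest VIF break ties towards
  the later column; the TSS threshold reports the smallest maximiser.
- Ensemble member order never affects predictions (asserted).

## Interfaces

The R functions are the primary interface; `run_pipeline()` executes the
whole analysis from a `run_config()` (or a YAML file via
`read_run_config()`), writing rasters, report tables, a run log and a JSON
manifest with config echo, stage counts and per-file checksums. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`, and
`scripts/acceptance.R` reproduces the headline quantities from scratch.

## Known limitations

- Geographic lon/lat with square cells only; no projections, resampling or
  multi-band formats.
- Five fixed algorithm families; no GLM/GAM/MaxEnt members and no
  hyperparameter search.
- The importance statistic reproduces the *kind* of permutation
  correlation metric used in ensemble SDM platforms, not any package's
  exact internals.
- Area percentages are cell fractions unless latitude weighting is
  switched on; at continental extents the difference is material.
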