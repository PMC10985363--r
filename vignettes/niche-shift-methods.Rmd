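---
title: "Quantifying climatic niche shifts and modelling invasive distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying climatic niche shifts and modelling invasive distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

## The question

When a species is introduced outside its native range, does the invading
population occupy the same climate it occupied at home, or does it shift into
novel conditions? `nicheshift` answers this in *environmental* space: the
climates of both ranges are projected onto the first two axes of a principal
component analysis, the density of occupied and available conditions is
estimated on a common grid, and the two occupancy surfaces are compared. A
second, complementary question — where else could the species establish? — is
answered in *geographic* space with an ensemble distribution model.

Because real invasion data (occurrence archives, global climate rasters) are
large, snapshot-dependent and externally hosted, the package ships a
virtual-species simulator whose niche-shift structure is known analytically.
Every method in the package is exercised and tested against those controlled
scenarios.

## Niche quantification

### Accessible areas

Each range's *background* is the minimum convex polygon around its (cleaned
and thinned) occurrence records, buffered by one degree and intersected with
the cells holding climate data. The buffer width (default 1 degree) delimits
the area plausibly reachable by dispersal; all availability densities are
computed over these cells only. Regions with fewer than `min_occurrences`
(default 20) records are flagged and skipped rather than compared — a handful
of points cannot support a density estimate, only a misleading one.

### PCA-env

Climate layers are z-transformed (mean 0, unit sd, `n - 1` denominator) over
the *union* of the two backgrounds, and a covariance PCA is calibrated on
those pooled cells with equal weight per cell. Both backgrounds and both
occurrence sets are then projected onto PC1-PC2. Calibrating on the pooled
available environment (rather than on occurrences, or on one range) is what
makes the two ranges commensurable: a cell's score means the same thing on
both sides of the comparison. Loadings signs are canonicalized (the
largest-magnitude loading of each component is made positive) so that
repeated runs produce identical axes.

### Occupancy grids

The PC1-PC2 plane is gridded at resolution `R = 100` per axis; the bounds are
the pooled background score range plus a 5% margin, shared by both ranges so
the grids are cell-by-cell comparable. On this grid we estimate

* `o` — kernel density of the range's occurrence scores,
* `e` — kernel density of its background cells (available environment),
* `z` — occupancy: `o / e` where `e > 0`, 0 elsewhere, rescaled to max 1.

The kernel is Gaussian with Silverman's rule-of-thumb bandwidth per axis,
computed on the point set being smoothed, and *truncated at three
bandwidths*. Truncation matters: it gives the density exact zeros outside
the data envelope, so "conditions the species does not occupy" is a
well-defined set of cells rather than a numerical fuzz of 1e-30s. That set
is load-bearing for the decomposition below and for exact zero overlap
between genuinely disjoint niches. The availability correction (`z = o/e`)
is the default because the framework contrasts *occupied* against
*available* conditions; the uncorrected variant (`correction = FALSE`) is
kept for sensitivity analysis.

### Overlap, similarity, decomposition

**Schoener's D** between two occupancy grids normalized to sum 1:
`D = 1 - 0.5 * sum |z1 - z2|`, 0 = disjoint, 1 = identical.

**Similarity test.** The invaded occupancy pattern is displaced so its
centre of mass lands on a uniformly drawn cell of the invaded background,
re-truncated to the available environment, and D is recomputed; after
`n_iter = 100` displacements, `p = (count(D_null >= D_obs) + 1)/(n_iter + 1)`.
The test is one-tailed for similarity and ties count toward the null, so the
smallest attainable p at 100 iterations is 1/101 ≈ 0.010. The randomization
is directional (native → invaded): only the invaded niche is displaced,
within its own background.

**Expansion / stability / unfilling.** Computed inside the *analog climate*:
cells where both availability densities exceed their own `analog_quantile`
(default 0.10) quantile of positive values, i.e. conditions genuinely
present in both ranges. Within that region,

* expansion = share of invaded occupancy on cells where the native niche is
  empty (`z_native = 0`),
* stability = 1 − expansion (an identity, asserted on every run),
* unfilling = share of native occupancy on cells the invader never occupies.

Shares are density-weighted by default, matching the "proportion of the
niche" reading; `binary = TRUE` counts occupied cells equally instead. An
empty analog region (or a niche with no mass there) yields `NA` with an
explanatory reason — never a silent zero. Both the weighting variant and the
analog threshold are recorded in the output, since different defensible
choices exist for each.

## The virtual-species simulator

`generate_climate_stack()` builds pseudo-bioclimatic layers by smoothing
seeded Gaussian noise with a Gaussian kernel of sd `autocorr_range` cells and
linearly mixing the standardized fields through a factor of the target
correlation matrix, so the imposed inter-layer correlations are exact in
expectation and the linear unit scaling (temperature-like for `Bio1..Bio11`,
precipitation-like beyond) preserves them. A smoothed threshold field
supplies a shared land/sea mask covering 10-30% of cells. One integer seed
drives everything through derived sub-streams, so identical calls are
byte-identical.

A `virtual_species()` responds to each layer with an independent Gaussian:
suitability 1 at the optimum, `exp(-0.5)` one breadth away, truncated to
exactly 0 beyond 6 breadth units. `sample_occurrences()` draws cells without
replacement with probability proportional to suitability and jitters each
point uniformly within its cell (no artificial duplicate coordinates, no
sub-cell information pretended).

`make_scenario()` assembles the controlled comparisons. Two disjoint
geographic regions — the west and east 45% column bands of one stack — share
their environmental distribution by construction, which is exactly the
situation the niche metrics are meant to see: geographic separation without
environmental separation. The native species sits at the pooled
environmental centroid of the first two layers with breadth 0.4 pooled sd
per axis; the invaded species is derived by the scenario kind (identical;
shifted by `magnitude` breadths; shifted with halved breadth; separated by
at least 6 breadths; shifted diagonally). Defaults of 300 occurrences per
region reflect a mid-sized post-thinning occurrence set. Two-layer stacks
are recommended for scenario work: PC1-PC2 is then a rotation of the
generating environment space, and the recorded truth and the estimate live
in the same plane.

The recorded truth integrates the two Gaussian suitabilities over each
region's cells, with niche support cut at 3 breadth units
(suitability ≥ exp(−4.5)) — deliberately mirroring the 3-bandwidth kernel
truncation of the empirical grids, so truth and estimate share one
definition of "occupied conditions". `expected_stability +
expected_expansion = 1` holds exactly by construction.

What the simulator does *not* emulate: dispersal limitation and spatial
aggregation beyond climate, observation effort gradients, taxonomic error,
coastline geometry, and non-Gaussian (skewed, bimodal, interactive)
responses. Passing tests therefore demonstrate that the estimators recover
known structure under clean sampling — not that any real invasion analysis
is free of those complications.

## The ensemble distribution model

`sdm_ensemble()` models one species over all valid cells of a stack:

1. **CELLSIZE thinning** to one record per raster cell.
2. **Predictors**: covariance PCA of the z-transformed layers; the minimal
   leading components reaching 95% cumulative variance.
3. **Pseudo-absences** (1:1 with presences) drawn uniformly from the
   *low-suitability stratum*: cells whose bioclim envelope score (per-axis
   percentile depth `1 - 2|F(x) - 0.5|`, minimum across predictors) falls
   below the median presence-cell score, and at least `min_distance_cells`
   (default 10) from any presence cell. The default radius equals the
   spatial autocorrelation scale of typical climate grids: a pseudo-absence
   inside the correlated neighbourhood of a presence is an environmental
   near-duplicate of a presence carrying the opposite label, which poisons
   both training and evaluation.
4. **BLOCK folds**: the point bounding box is tiled into square blocks
   assigned to 4 folds in a checkerboard (auto-sized so every fold holds at
   least 5% of presences), geographically separating evaluation from
   training.
5. **Algorithms**: MXS — a penalized maximum-entropy model, implemented as
   ridge logistic regression on linear + quadratic features with the penalty
   chosen by internal cross-validation; SVM (radial); RDF (random forest);
   BRT (gradient-boosted trees, 150 rounds, depth 3, learning rate 0.1).
   All run behind one train/predict contract and return suitabilities in
   [0, 1].
6. **Evaluation**: per fold, predictions are binarized at the threshold
   maximizing the Jaccard index `TP/(TP + FP + FN)` on the training points
   and scored on the held-out fold. The same rule thresholds the final map.
7. **Ensemble**: cell-wise mean weighted by each algorithm's mean fold
   Jaccard (weights normalized to sum 1); the ensemble's own fold-wise
   Jaccard (the `WMEA` column of the evaluation table) is computed from the
   weighted fold predictions.
8. **Occurrence constraint**: rook-adjacent connected components of the
   binary map are kept only if they contain a presence cell — suitable but
   unreachable patches are dropped a posteriori.

## Numerical choices and degenerate inputs

* Distances between occurrence records use the haversine formula on a
  6371-km sphere; thinning repeats 10 randomized elimination passes and
  keeps the best, ties resolved by lowest pass index; records are
  canonically sorted first so results are independent of input order.
* Zero-variance layers are dropped from standardization with a warning;
  fewer pooled background cells than variables is an error.
* Fewer than 3 non-collinear points: the background falls back to a
  point-buffer union, with a warning.
* Quantiles use R's type-7 default throughout.
* A training fold with one class, constant predictors, or an exhausted
  pseudo-absence stratum stop with explanatory errors rather than degrading
  silently.
* Problem sizes used in the shipped tests — 100-200 cells per side, 60-300
  occurrences per region, 1-100 permutation iterations, 20 recovery seeds —
  were chosen as the smallest sizes at which the estimators' sampling noise
  is clearly below the tolerances being asserted.

## File formats

Climate stacks are read and written as per-layer ESRI ASCII grids
(`.asc`, plain text, understood by every mainstream GIS) with a JSON sidecar
fixing layer order and CRS; occurrence tables as
`species,longitude,latitude,range` CSV; scenario truths and run
configurations as JSON; niche grids as JSON; reports as CSV rounded to 3
decimals with a full-precision sidecar.

## Known limitations

* The similarity test displaces the whole occupancy pattern rigidly;
  configurations where the invaded background is strongly non-convex can
  make some displacement targets nearly empty, which the test handles by
  re-truncation but at reduced effective randomization.
* The availability correction `o/e` amplifies occurrence density at the
  margin of the available environment where `e` is small; comparisons should
  use the same correction setting on both sides (the package enforces this).
* Envelope-constrained pseudo-absences are label-noisy for species whose
  niche uses only a small subset of the predictor axes: the min-aggregated
  envelope can score genuinely suitable cells as "low". This is a property
  of the method, visible in the simulator, and the reason evaluation scores
  on weak-signal species should not be read as model failure.
* E/S/U proportions are estimates from kernel densities; with very few
  occurrences the analog region and the `z = 0` sets are unstable, which is
  why the minimum-occurrence rule skips rather than reports such regions.
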