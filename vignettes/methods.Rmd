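---
title: "Modelling snake distributions and human overlap: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling snake distributions and human overlap: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakeOverlap)
```

## The problem

Snakebite mitigation and snake conservation both need maps: where are
medically important venomous snakes likely to occur, how much do those
places overlap with human populations, and how will both change under
climate change? `snakeOverlap` implements a complete desk-scale version
of that analysis chain: from occurrence records and environmental
raster layers, through presence-background niche modelling, to
cost-distance-restricted range maps, the Snake-Human Overlap Index
(SHOI), climate-projection ensembles, range-shift vectors and model
validation. Because the real occurrence databases behind such analyses
are curated services rather than files, the package ships a
synthetic-data module that generates all inputs with known ground
truth, so every downstream stage is testable, including full
parameter-recovery experiments.

## The data model

Everything lives on a fixed axis-aligned WGS84 lattice (`GridSpec`),
by default 0.01 decimal degrees per cell (~1.1 km at the equator).
Cell (1,1) is the north-west corner; a point belongs to the cell whose
half-open interval `[west, east) x (south, north]` contains it, which
makes cell indexing round-trip exactly. Rasters (`GeoGrid`) carry
suitability, population density, accumulated cost distance and SHOI;
nodata cells are `NA` and never enter arithmetic. Occurrence records
(`OccurrenceSet`) carry a positional uncertainty in meters; after
snapping, at most one record per species per cell survives (the most
accurate one). Rasters are stored as plain-text ESRI ASCII grids with a
WKT `.prj` sidecar; polygons as GeoJSON. These text formats keep the
package self-contained and byte-reproducible; no binary geodata stack
is required.

## Occurrence pre-filtering

Two filters precede modelling. First, deduplication to one record per
cell at the working resolution. Second, an accuracy filter: each
species keeps only the 75% of its records with the smallest positional
uncertainty (`floor(0.75 n)` when fractional, i.e. conservative
retention), *unless* it has fewer than 20 records, in which case all
records are kept — below roughly 20 records, model accuracy degrades
faster than location error hurts. The filter is applied per species;
a global cut would let well-sampled species crowd out sparse ones.

## Variable screening

Candidate environmental variables are screened twice:

* **Collinearity** (`collinearityFilter`): pairwise Pearson
  correlations are computed on background-sample values (not on full
  rasters — cheaper, and it is the background that the model actually
  sees). Of every pair with |r| > 0.8 the lower-priority variable is
  dropped, except pairs explicitly whitelisted via `keepOverrides`
  (mirroring variable pairs kept for biological reasons despite
  collinearity). Constant variables are excluded with a warning.
* **Permutation importance** (`reduceVariables`): after a first
  "starting" model, each variable's importance is measured by
  permuting its column and recording the drop in training AUC,
  averaged over the cross-validation replicates and normalized to sum
  to 100. The reduced model keeps the top five variables
  unconditionally, plus any variable with importance >= 1% whose rank
  does not exceed `floor(n_records / 20)` — balancing predictor count
  against data volume. Rank ties break by variable name for
  determinism.

## Target-group background

Presence-only models are only as good as their background sample. The
package uses a *target-group* background: the pool of all occurrence
records of the wider taxon (which carry the same roads-and-towns
sampling bias as the presences) restricted to a buffered box around the
modelling unit's occurrences. The buffer width equals the larger of the
latitudinal and longitudinal occurrence extents (the latter measured at
the mean latitude), clamped to 1000-3000 km; the box geometry is a
rectangular expansion, with km-to-degree conversion on a sphere of
radius 6,371,000 m (the same Earth model used by the shift vectors).
The minimum clamp prevents unrealistically small backgrounds for
range-restricted species; the maximum keeps the background within the
area plausibly available over recent biogeographic history.

## The niche model

The model is a Maxent-style penalized Gibbs distribution over the
background-plus-presence cells:

$$ p(x) = \frac{\exp(w \cdot f(x))}{\sum_{x'} \exp(w \cdot f(x'))} $$

with feature vector $f$ containing linear and quadratic terms
(standardized), pairwise products (optional), and forward/reverse
hinge features at 10 evenly spaced knots per variable over the
training range. Product features are withheld for data-sparse (< 80
records) *and* naturally restricted (buffer at the minimum clamp)
units, where they invite overfitting. The weights maximize the
L1-penalized presence log-likelihood; the per-feature penalty is
$\lambda_j = \beta \, \mathrm{sd}_{presence}(f_j) / \sqrt{n}$ with
$\beta = 1$, floored at 0.05 (0.5 for hinge features — hinges active
only in the far tails of the presence distribution otherwise carry a
near-zero penalty and absorb spurious weight; 0.5 is the sd ceiling of
a [0,1]-valued feature and matches the conservative hinge
regularization of the reference Maxent implementation).

**Optimization.** The objective is convex. It is solved by proximal
Newton: each outer iteration builds the exact quadratic model of the
log-normalizer, solves the L1-penalized quadratic subproblem by cyclic
coordinate descent, and applies the step with halving on the true
objective and a trust-region cap. Convergence is declared when the
objective changes by less than 1e-8 (cap: 500 outer iterations;
non-convergence is an error, not a silent result). The Hessian is
damped because some features are exactly collinear by construction
(the hinge at the training minimum is an affine image of the linear
term).

**Output scale.** Predictions are reported on the logistic scale with
default prevalence 0.5: `plogis(eta + H)` where `eta` is the
log-density link and `H` the entropy of the fitted density — the
familiar 0-1 habitat suitability index. Before feature evaluation,
every variable is clamped to its training range, so projections never
extrapolate beyond conditions seen in training; predictions are
invariant to affine rescaling of any input variable.

**Cross-validation.** "10-fold cross-validation with 70/30 splits" is
implemented as 10 independent random 70/30 presence splits with shared
background, matching the stated percentages (a literal 10-fold
partition would give 90/10).

**Thresholding.** The balance threshold minimizes
`6*trainingOmission + 0.04*cumulative + 1.6*fractionalPredictedArea`
over all observed suitability values, where `cumulative` is the
percentage of raw Gibbs density below the candidate threshold. The
coefficients follow the published Maxent "balance" rule. After
thresholding, surviving cells are divided by their maximum so every
species' map peaks at 1 and maps are comparable across species.

## Cost-distance restriction and MU splitting

A suitability map says where conditions are right, not where the
species actually is. To remove disconnected and overly remote habitat,
accumulated cost distance from the known occurrences is computed on
the 8-connected lattice with per-cell resistance `1 / max(suit, floor)`
and step cost `len * (r_i + r_j) / 2` (`len` = 1 rook, sqrt(2)
diagonal). One cost distance unit (CDU) is one rook step through
perfect habitat. The phrase "cost proportional to suitability" would
make good habitat costly, so resistance is taken as the *reciprocal*
of suitability, consistent with the conductance framing of the
least-cost literature; the floor (1e-6) keeps zero-suitability cells
passable but extremely expensive. CDU is measured in cell units, so the
default 500-CDU cut is calibrated to 0.01-degree cells. Cells beyond
500 CDU are zeroed; the unclipped map is kept alongside, because
"suitable but unconfirmed" habitat is exactly where new records tend
to appear. Costs are computed on the raw (pre-threshold) surface:
thresholded zeros would create infinite-resistance barriers.

Multi-species modelling units are split by assigning each cell to the
member species with the lowest cost distance. Within a 500-CDU overlap
allowance the two lowest-cost species share the cell with weights
`w_s = cd_other / (cd_s + cd_other)` — both at 250 CDU means both
halved; at 100 vs 300 CDU the closer species keeps 0.75. Any third
species within the allowance is excluded (the pairwise rule is the only
one defined; generalizing it further would be invention). Downweighted
values below the unit's original balance threshold are re-zeroed,
which removes low-confidence slivers in contact zones.

## SHOI

The Snake-Human Overlap Index multiplies suitability by log human
population density: `SHOI = suit * ln(1 + pop)`, per cell. The `+1`
shift is a deliberate deviation from a bare logarithm, which is
undefined at zero population and negative below one person per cell;
with the shift, SHOI is zero exactly where either factor vanishes and
non-negative everywhere, while preserving the logarithmic damping of
dense cities. Group summaries use the cellwise maximum (closely
related species whose suitability is not additive in contact zones);
cumulative surfaces and richness counts use sums over species.

## Futures, change metrics and shift vectors

Projections are made per GCM (the design anticipates an ensemble of
seven) by replacing only the climate layers and clamping as always.
Ensembles are summarized cellwise as the median (most likely), 10%
quantile (minimum likely) and 90% quantile (maximum likely), with the
linear-interpolation quantile. Change metrics — range size, expansion
(newly suitable cells), contraction (newly unsuitable cells), total
suitability, total SHOI — are computed on thresholded maps, where
"suitable" means value > 0; the bookkeeping identity
`future = current + expansion - contraction` holds by construction and
is property-tested. Range-shift vectors connect the current and future
range centroids (unweighted means of suitable cell-center coordinates,
taken on unprojected lon/lat exactly as the field does, accepting
metric distortion at high latitude). Distance is the haversine
great-circle distance on a sphere of radius 6,371,000 m; direction is
the initial bearing in (-180, 180]. Regional summaries use the
circular median of bearings (minimizing summed circular distance;
among ties the circular mean of minimizers, so bearings {350, 10}
summarize to 0) and the ordinary median of lengths.

## Validation

* **AUC**: rank-based (Mann-Whitney), ties counted half.
* **Partial ROC** (`partialRoc`): 39 iterations; each draws 50% of the
  occurrences and an equal number of random data cells, builds the
  curve of (fractional predicted area, 1 - omission) at thresholds
  placed at every 1% of predicted area, and records the ratio of the
  two curve areas. No omission-error cap is applied (the plain
  description of the method, not the capped variant). The p-value is
  the fraction of iterations with ratio <= 1, a one-sided test against
  chance. Constant surfaces are refused as degenerate.
* **EDR comparison** (`edrCompare`): against expert-derived range
  polygons (rasterized by cell-center containment), commission is the
  percentage of suitable cells outside the EDR, congruence the
  percentage inside (they sum to 100), and omission the percentage of
  EDR cells left unsuitable.

## The synthetic world

The generator module emulates, with known truth: spatially
autocorrelated environmental layers (Gaussian-filtered white noise,
bandwidth 8 cells, standardized), designed collinear pairs
(`layer_j = layer_i + 0.5 * independent noise`, giving |r| ~ 0.89 so
the screening filter is exercised), a logistic true-suitability
surface, presence points sampled proportional to truth times a
sampling-bias field (a road-like diagonal gradient, 10:1 effort ratio,
which is what makes the target-group background correction testable),
lognormal positional uncertainties with median 100 m (exercising the
accuracy filter), clustered lognormal population density, per-GCM
future perturbations (prescribed mean delta plus smoothed GCM-specific
noise; non-climate layers held constant), and expert-range polygons
traced from the truth surface.

What the synthetic world does *not* emulate: real climate covariance
structure, real snake biology, irregular coastlines and true ocean
masks, spatially varying record quality, or taxonomic uncertainty.
Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct and unbiased under its own assumptions — not that
any particular real-world map is accurate.

**Recovery harness conditions.** The parameter-recovery experiment
uses a 200 x 200 grid, 200 presences, sampling bias on, and a
*restricted* species: a logistic truth surface with landscape
prevalence ~0.14 (one strong linear driver, one quadratic driver, two
inert layers including a designed collinear twin). The restricted
regime is the scientifically relevant one — the data-poor,
range-restricted taxa are exactly the ones such pipelines exist for —
and it is the regime in which a niche is discriminable at all: for a
near-ubiquitous species even the true suitability surface cannot
separate presences from background (the information ceiling on AUC
falls toward 0.5 as prevalence grows), so recovery targets would be
unattainable for any method. Under these conditions the pipeline's
Spearman correlation with truth is ~0.96 and held-out AUC ~0.86,
essentially at the truth surface's own ceiling.

## Problem sizes and numerical choices

Tests run the full pipeline at 50 x 50 cells (3 GCMs, 1 future step, 3
CV splits) and the recovery harness at 200 x 200 — sizes chosen so the
whole suite completes in well under a minute while every code path,
including the end-to-end determinism check (two runs, byte-identical
outputs), is exercised. Other numerical choices: optimizer tolerance
1e-8 / 500 iterations; resistance floor 1e-6; quantile type 7 (linear
interpolation); dedup ties broken by record order; importance-rank
ties by variable name; rasters written with 17 significant digits so
write/read round trips are bit-exact; all stage seeds derived
deterministically from one master seed.

## Known limitations

* The CDU cut is resolution-dependent by design; at other cell sizes
  the default of 500 needs recalibration.
* The fade-out rule is defined pairwise; with three or more species
  within the allowance the two lowest-cost species share the cell and
  the rest are excluded.
* Backgrounds are rectangular boxes, not dissolved per-point buffers;
  there is no ocean masking beyond nodata cells and no reprojection
  between CRSs.
* Permutation importance is AUC-based; gain-based importances can rank
  correlated variables differently.
* Future population density and land use are held constant; only
  climate layers change between time steps.
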