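---
title: "Mapping the representativeness of tropical field sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the representativeness of tropical field sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropirep)
```

## The problem

Field research across the terrestrial tropics is not distributed evenly:
some biomes and environmental conditions are sampled and cited intensively
while others are nearly absent from the literature. `tropirep` quantifies
this imbalance from a geocoded literature database — one row per (article,
sampling location), with the article's citation count and up to three
habitat labels per location — together with a biome/ecoregion polygon layer
and an aligned stack of environmental rasters (mean annual temperature MAT
in °C, annual precipitation MAP in mm, their projected end-of-century
anomalies ΔMAT and ΔMAP, leaf area index LAI in m² m⁻², soil organic carbon
stock SOC to 2 m depth, and vascular-plant and bird-plus-mammal species
richness).

Three complementary views are produced:

1. **Zonal summaries.** Each article's citations are split equally across
   its sampling locations (`allocate_citations()`), locations in urban or
   agricultural habitats are removed (`filter_natural_habitats()`), the
   remainder is clipped to a buffered tropical domain and labeled by biome
   (`assign_locations()`), and `biome_summary()` tabulates per-biome area,
   location and citation shares, densities per 10⁵ km², and the
   citation:sampling ratio (percent citations over percent locations).
2. **Environmental-space frequencies.** `env_space_comparison()` bins a
   large random background sample of domain pixels, the sampling locations,
   and the citation weight over pairs of environmental axes on shared bin
   edges; a representative literature would reproduce the background
   surface up to scale.
3. **A representativeness map.** A presence/pseudo-absence ensemble — a
   binomial penalized-spline additive model, a probability random forest,
   and gradient-boosted trees — is trained to discriminate sampled
   locations from random domain cells. The cellwise **median** of the three
   member probabilities is the representativeness surface; cells above 0.5
   count as "covered" by current sampling, and the covered area is
   summarized on the sphere.

## The model and its assumptions

Sampling locations are treated as presence records of the process "field
research happens here". Because only presences are observed, an equal
number of pseudo-absences is drawn uniformly from domain cells (cells
containing a presence are excluded by default, to avoid contradictory
labels; `exclude_presence_cells = FALSE` restores unconstrained sampling).
The binary response is modeled from the screened covariates; the ensemble
median is used rather than any single learner so that no one model family's
inductive bias dominates the map. The approach assumes that

* the covariates capture the environmental axes along which sampling is
  biased (a location process driven by, say, road access will be captured
  only insofar as accessibility correlates with the covariates);
* a uniform random background is the right null for "no preference";
* equal class sizes are appropriate — the fitted probability is then a
  relative preference, not an absolute sampling rate.

Covariates first pass `collinearity_screen()`: pairwise Pearson
correlations are computed and, while any pair has |r| at or above 0.70, the
member of the worst pair with the larger mean absolute correlation to the
other retained covariates is dropped. Pearson correlation is used because
the screen protects the additive model's smooth terms from concurvity-like
instability, a second-moment phenomenon.

Performance is assessed by repeated stratified random splits
(`cross_validate()`, default 99 permutations): 70% of each class trains the
ensemble, the held-out 30% is scored by the ensemble median, and the AUC —
the probability that a random presence outscores a random absence, ties
counted half — is recorded per split. Stratification by label is a design
choice (a plain random split can produce single-class partitions in small
tables); the 70% share is interpreted as the training portion, the usual
reading of such splits.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `buffer_km` | 100 | km | transition fringe around the formally tropical biomes; measured as great-circle distance so kilometres mean kilometres at every latitude |
| `excluded_habitats` | urban, agricultural | — | restricts the analysis to relatively natural environments |
| `n_background` | 100 000 | pixels | background sample describing ambient conditions; capped at the domain size with a warning |
| `collinearity_threshold` | 0.70 | \|r\| | retained covariates stay below this pairwise correlation |
| `window` (`focal_fill()`) | 19 | cells | moving-window mean used once to fill LAI gaps |
| `n_perm`, `train_frac` | 99, 0.7 | — | cross-validation permutations and training share |
| `threshold` | 0.5 | probability | strict `>` classifies a cell as covered |
| `gam_k` | mgcv default | basis size | smoothness selected automatically per covariate |
| `rf_trees` | 500 | trees | stable probability forest |
| `gbt_rounds`, `gbt_eta`, `gbt_depth` | 1000, 0.01, 3 | — | slow-learning shallow boosted trees |

All of these are arguments of `pipeline_config()` / `ensemble_config()` and
are echoed into the run manifest together with every derived stage seed, so
a run is reproducible from its manifest alone.

## The synthetic study system

`synthetic_config()` + `gen_stack()` / `gen_biomes()` / `gen_literature()`
generate a complete, self-consistent study system so every stage is
testable without downloads:

* **Covariates** are Gaussian-smoothed white-noise fields (correlation
  length `smoothness_cells`, default 6 cells) mixed through the Cholesky
  factor of a target correlation matrix, then shifted by a deterministic
  equator-to-margin gradient and scaled to realistic units (e.g. MAT ≈ 27
  °C at the equator declining by 0.22 °C per degree of latitude). The
  target correlations apply to the stochastic component; the default
  matrix couples MAP, LAI, SOC and the richness layers moderately. LAI
  receives a configured fraction (default 5%) of nodata gaps.
* **Biomes** threshold an independent smooth latent field into quantile
  classes over the tropical core (|lat| ≤ 23.4°); connected components are
  polygonized along cell edges, so the vector layer and the raster grid
  agree exactly.
* **Literature** is drawn from a point process over domain cells with
  intensity ∝ exp(Σᵢ βᵢ zᵢ(x)) on standardized covariates — the default
  β(LAI) = 0.8, β(MAT) = 0.3 emulates the real-world pull of research
  toward warm, densely vegetated forest sites. Locations per article are
  uniform on 1–4 (mean 2.5 locations/article); citations are discretized
  log-normal (meanlog 2.6, sdlog 1.2, so a typical article carries a few
  dozen citations with a heavy upper tail); 36% of locations are marked
  urban/agricultural, matching the share of human-modified habitats that
  motivates the natural-habitat filter.

What the generator does **not** emulate: real geography (continents,
coastlines, road networks), the clustering of locations around research
stations beyond what the covariate bias induces, spatially structured
citation practices, and the exact value distributions of the global raster
products. Passing tests therefore demonstrate that the pipeline's
arithmetic, bias recovery and calibration are correct under a known
preferential-sampling mechanism — not that any particular real-world
dataset is unbiased.

## Numerical choices

* **Areas** are computed on the authalic sphere (R = 6371 km): grid cells
  by the latitude-band closed form R²Δλ(sin φ₂ − sin φ₁), polygons by
  spherical excess (`geosphere`), with nested rings treated as holes by
  even-odd depth.
* **The domain buffer** is evaluated on the analysis grid: a cell joins
  the buffer when its center lies within `buffer_km` (haversine) of a core
  boundary cell center. This keeps the buffer metric in kilometres without
  a projection library; its resolution is one cell, so the grid should be
  finer than the buffer distance.
* **Point-in-polygon** is even-odd ray casting with points on a ring edge
  counting as inside; overlapping units resolve to the earliest unit in
  layer order. Both rules make assignment deterministic.
* **Focal fill** is single-pass: freshly filled values never feed later
  fills in the same pass, so the result is independent of traversal order.
  An explicit `passes` argument repeats the fill for workflows that want
  cascading.
* **Binning** uses right-open bins with a right-closed final bin, so the
  pooled min and max (edges padded by 0.1%) always land inside the grid;
  out-of-range and missing rows are counted, keeping binned plus dropped
  mass equal to input mass to 1e-9.
* **Percentages** are computed on unrounded values; displayed ratios are
  rounded half-away-from-zero to one decimal (base `round()`'s banker's
  rounding would map 0.25 to 0.2).
* **Citation re-allocation after filtering** defaults to recomputing
  total/n over the *remaining* locations, so every retained article keeps
  its full citation weight; `reallocate = FALSE` keeps the original
  per-location allocations instead. Both conventions conserve
  interpretable totals; the choice is exposed because either is defensible.
* **Seeds**: one master seed; every stochastic stage derives its own seed
  by hashing the stage name, so stages are independent and reruns are
  bit-identical. Grid generation, background draws, pseudo-absences and
  every CV split are reproducible from the manifest.

## Design choices

The package stores rasters in a small matrix-backed `env_grid` class with
plain-text I/O (ESRI ASCII grid plus a JSON stack manifest) and polygons as
ring lists with GeoJSON I/O. These formats round-trip exactly, diff cleanly
under version control, and carry no binary dependencies; the co-registration
validator rejects misaligned stacks rather than resampling, keeping
regridding explicitly out of scope. The gradient-boosted member is fitted
with xgboost (binary logistic objective) and the additive member with
`mgcv::bam(discrete = TRUE)`, which fits the identical penalized-spline
model class at a fraction of the cost — relevant because cross-validation
refits the ensemble 99 times.

## Problem sizes

The test-suite and acceptance runs use deliberately desk-scale sizes: grids
of roughly 60 × 40 to 120 × 128 cells at 0.5–1°, a few hundred synthetic
articles (≈1000 locations), background samples of 1500–10 000 pixels, and
presence/absence tables of ≈1100–2000 rows; calibration checks
(permuted-label null in [0.45, 0.55], separable data ≥ 0.95) run the full
99-permutation cross-validation at n = 2000. These sizes give stable Monte
Carlo behavior for every property tested while keeping a complete run in
minutes on one core.

## Known limitations

* The buffered domain is raster-based; vector-exact buffering would need a
  geodesic geometry engine and would change areas by at most one cell
  width along the boundary.
* Printed location/citation densities from published zonal tables are not
  exactly recoverable from percentage columns and a single domain area
  when the underlying per-biome area base differs from the printed shares;
  the summary therefore treats densities as formula-defined outputs
  (weight per 10⁵ km² of the biome's area) and pins its identities to the
  percentage and ratio columns.
* The ensemble's probability is a relative preference under equal class
  sizes, not an absolute sampling rate, and inherits any bias present in
  the covariate products themselves (notably modeled richness surfaces).
* Spatial autocorrelation is not accounted for in the random CV splits;
  spatially blocked validation is out of scope.
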