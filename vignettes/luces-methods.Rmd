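---
title: "Modelling land-cover change and ecosystem-service trade-offs with luces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling land-cover change and ecosystem-service trade-offs with luces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luces)
```

## The problem

Rapid urbanisation converts cropland and vegetated land into built-up land,
and that conversion reshapes the supply of ecosystem services: carbon
storage shrinks, water yield rises (built-up surfaces evapotranspire
little), habitat degrades, crop production moves. Because the services
respond in different directions, planning questions are really questions
about *trade-offs and synergies between pairs of services under alternative
development scenarios*. `luces` implements that whole chain as a tested
pipeline: a Markov-chain cellular-automata (Markov-CA) land-cover change
model, six equation-based ecosystem-service valuation models, and the
trade-off/synergy degree (TSD) index that quantifies pairwise interactions,
all exercised on synthetic landscapes with known ground truth.

## Data model

All rasters are matrices carrying a shared `grid_geometry` (rows, columns,
cell size in metres, lower-left origin, nodata sentinel). Land cover uses
six integer codes (`lc_classes()`): 1 cropland, 2 forest, 3 grassland,
4 wetland, 5 built-up, 6 bare. Cell `[1, 1]` is the top-left map cell;
areas always come from cell counts times cell area, never from vector
geometry. Any operation combining grids first verifies bit-equal geometry
and intersects nodata masks — the conservative choice when the sources
disagree about coverage.

File I/O uses the ESRI ASCII grid format, a plain-text raster format that
round-trips losslessly through `read_ascii_grid()`/`write_ascii_grid()`.
Composition percentages (`class_areas()`) are taken over the *classified*
total rather than a nominal administrative area, so they always sum to 100;
published composition tables are only internally consistent under this
convention.

## The land-cover change model

**Markov chain.** `estimate_transition_matrix()` cross-tabulates two maps
and divides each from-class row by its class area at the first date:
$P_{ij} = A_{i \to j} / A_i$. Classes absent at the first date get identity
rows. `project_demand()` propagates a class-area row vector through the
matrix power, $S_{t+n} = S_t P^n$, conserving total area to floating
precision. The interval the matrix was estimated over is carried as a
label; how many steps a projection takes (`n_periods`) is the caller's
choice, because observed-interval and projection-horizon lengths rarely
match and the Markov assumption is per-step.

**Transition potential.** For a chosen transition $i \to j$,
`fit_transition_potential()` fits binary logistic regression — changed
versus persisted among all class-$i$ cells at the first date — on
standardised driver rasters (slope, distances to major/minor roads and the
city centre, population density):
$\mathrm{TP}_x = e^z / (1 + e^z)$, $z = b_0 + \sum_i b_i x_i$.
The fit uses a seeded 70/30 train/test split and reports held-out ROC-AUC.
Coefficients are back-transformed to the raw driver scale, and the full-map
potential surface is returned. Quasi-perfect separation (non-convergence or
standardised coefficients beyond ±15) triggers a ridge-regularised
(`alpha = 0`) refit, flagged in the result.

**CA allocation.** `ca_allocate()` turns demanded class areas into a map.
Candidate cells are scored as
$\mathrm{TP} \times (\varepsilon + \Omega)$, where $\Omega$ is the fraction
of the neighbourhood window (default 5×5, edge-shrunk at borders) already
holding the target class and $\varepsilon = 0.05$ keeps isolated growth
possible. Growing classes are processed in descending order of net demand;
each takes its highest-scoring cells from classes with surplus area, a
converted cell leaves later candidate pools, and protected cells never
convert. Ties are broken by a seeded jitter of magnitude $10^{-9}$, so runs
are reproducible and the jitter cannot override a meaningful score
difference. When demand is infeasible under the masks the allocation is
partial and the shortfall is reported per class rather than silently
redistributed.

**Scenarios.** `scenario_spec()` encodes three rule sets.
*BAU* lets the historical trend run unmodified. *CP* (cropland protection)
converts grassland and forest on slopes below 6° — outside the core
districts — to cropland, then protects all cropland from conversion.
*ER* (ecological restoration) protects an ecologically sensitive mask from
conversion and reverts cropland steeper than 6° to a vegetated class.
"Ecologically sensitive" has no operational definition in the literature
this follows, so the mask is user-supplied; `run_study()` defaults to
forest/wetland cells plus slopes above 15°. After forced conversions,
demand for each class is capped at the area achievable under the
protection mask, with the shortfall reported.

**Validation.** `validate_map()` computes overall accuracy and Cohen's
kappa from the confusion matrix of a simulated against a reference map
(`e1071::classAgreement` under the hood; the tests recompute
$\kappa = (p_o - p_e)/(1 - p_e)$ by hand as an independent check).

## The six valuation models

| Service | Model | Units |
|---|---|---|
| Water yield (WY) | $(1 - \mathrm{AET}_x/p_x)\, p_x$ per pixel; the ratio is a per-class `aet_fraction` | t of water |
| Carbon storage (CS) | class areas × four carbon-pool densities | t |
| Soil conservation (SC) | RUSLE retention $R\,K\,L\,S\,(1 - C\,P)$ | t |
| Crop production (CP) | district totals apportioned to cropland pixels by NDVI share | t |
| Air purification (AP) | class areas × PM10 removal rate | t PM10 |
| Habitat quality (HQ) | $H_k\,(1 - D^z/(D^z + S^z))$ | dimensionless (pixel sum) |

Design choices where the source methods leave gaps:

* **AET.** Only the ratio AET/p enters the water-yield equation, so the
  model takes it directly as a per-class parameter instead of embedding a
  Budyko-type evapotranspiration model. That keeps the equation exact and
  makes the (externally sourced) parameterisation explicit configuration.
* **RUSLE L and S.** S uses the McCool piecewise slope factor on Horn
  slope, floored at 0.03 on flat terrain so retention is well-defined
  everywhere; L uses a single-cell slope length (`cell_size`), avoiding
  flow-accumulation modelling. R and K are input rasters
  (`constant_grid()` is a convenience for spatially uniform values).
* **Habitat threats.** Defaults: threats are built-up and bare land, linear
  distance decay with `d_max` 3000 m, weights 1 and 0.5, half-saturation
  0.5, exponent 2.5 — standard InVEST-style conventions, all overridable
  via `threat_spec()`. At threat level equal to the half-saturation
  constant, quality halves for any exponent — one of the tested
  identities.
* **HQ totals** are pixel sums (dimensionless); published tables are
  ambiguous between sums and means, and the sum is what the record stores.
* **Scenario crop production.** Simulated futures have no NDVI, so
  `scale_crop_production()` scales each district's base-year production by
  its cropland-area ratio. This convention is isolated in one function.
* **Relative change** is always $(V_{t2} - V_{t1})/V_{t1}$ for both
  services, with a zero baseline an explicit error rather than an Inf.

## The TSD index

For two services with relative changes $\Delta_i$, $\Delta_j$ over the same
interval:

$$\mathrm{TSD}_{i,j} = \begin{cases}
0 & \Delta_i \Delta_j = 0\\
+\left|\ln\left|\Delta_i/\Delta_j\right|\right| & \Delta_i \Delta_j > 0 \text{ (synergy)}\\
-\left|\ln\left|\Delta_i/\Delta_j\right|\right| & \Delta_i \Delta_j < 0 \text{ (trade-off)}
\end{cases}$$

The statistic is symmetric in the pair, invariant to a common positive
scaling of both deltas, and flips class (with preserved magnitude) when
exactly one delta changes sign — all property-tested. Two boundary
conventions are documented rather than silent: equal-magnitude changes give
a value of 0 with the sign-based class retained ("relationship present,
magnitude zero"), and one-sided zero change is classed "none".

`tsd_matrix()` applies the index to all 15 unordered pairs of the six
services, in the canonical order CS, WY, SC, HQ, CP, AP. `spatial_tsd()`
maps the index by aggregating service rasters into non-overlapping blocks
(default 10×10 cells) before computing per-block deltas — per-pixel ratios
would divide by zero wherever a pixel's baseline is zero, which is common
(e.g. crop production off cropland). Blocks with a zero baseline in either
service are flagged nodata. Block aggregation is a documented stand-in for
the unspecified construction of published trade-off maps, not a claim about
how those maps were made.

## Synthetic landscapes as ground truth

No real classified imagery ships with the package; every input is
generated:

* `generate_landcover()` grows contiguous patches from quota-assigned
  nuclei (about one per `patch_size`² cells), so realised class shares
  track the target composition (within ±2 percentage points at 100×100 and
  up) while remaining spatially clustered — the property CA neighbourhood
  effects need. Per-cell iid sampling would satisfy the composition but
  exercise nothing spatial.
* `evolve_landcover()` changes each cell by row-wise multinomial sampling
  from a prescribed transition matrix, so the Markov estimator has an exact
  oracle; an optional `driver_mod` makes one transition's probability a
  logistic function of covariate grids with known coefficients, so the
  logistic-regression stage has a recoverable ground truth.
* `generate_terrain()` rescales Gaussian-filtered white noise to a target
  relief; `generate_fields()` builds precipitation (positive, mild
  gradient), class-conditional NDVI, centre-decaying population density and
  exact Euclidean distances to seeded road polylines.

Every generator draws from one seeded stream per call and never touches
global RNG state.

What passing tests on these landscapes do *not* show: realistic
geomorphology, hydrology, road-network growth, or calibration to any real
region. The generators establish that the estimators recover what was
planted, not that the defaults describe a particular city.

### Test and study problem sizes

The shipped study (`study_config()`) uses a 120×120 grid at 100 m with the
class composition of a published 2005 urban case study, one simulated
decade, and one 15-year projection step — large enough for stable service
totals and a meaningful hindcast kappa, small enough to run in about a
second. Recovery tests use 300×300 (transition matrix, tolerance 0.02 on
any entry) and 160×160 with an all-cropland base (logistic regression,
≥ 20,000 fit cells, 20% coefficient tolerance). The transition-matrix
recovery test uses a balanced composition (1/6 each): its tolerance is a
sampling-error bound, and a class at a 1% share of a 300×300 grid
contributes only ~900 source cells, where binomial error alone approaches
the bound.

## Numerical conventions

* Row-stochasticity, fraction sums and area conservation are checked to
  1e-9; crop-production conservation is tested to 1e-9 relative.
* Demand is met within one cell's area per class whenever feasible;
  rounding demand to whole cells is the only discretisation.
* Horn slope at borders uses edge replication; a plane's interior slope is
  exact.
* Degenerate inputs fail loudly: all-nodata maps, zero-NDVI districts with
  cropland, zero baselines in relative change, non-stochastic matrices,
  demand exceeding the map.

## Reproducing published arithmetic

`nanjing_reference_values()` embeds the printed land-cover and service
numbers of the published Nanjing case study (2005–2015, scenarios to 2030)
together with per-row tolerances (half of the last printed digit, wider
only where the source itself is rounded or truncated — each such row says
so in its `source` label). `check_reference_arithmetic()` recomputes every
derivable percentage, net change, share and TSD value with the package's
own functions and reports pass/fail per row. Two rows deserve note: the
2005 built-up share is printed inconsistently with its own area and is
omitted, and the ER built-up percentage has no printed absolute, so its row
checks the implied value and is labelled as such.

## Known limitations

* No map projection, resampling, or vector processing; one geometry per
  analysis.
* No GeoTIFF I/O; the ASCII grid format is the interchange surface.
* The CA is a single-step allocator per projection period, not an annual
  iterator; multi-period dynamics come from `n_periods` Markov steps.
* Monetary valuation, Budyko water yield, flow-accumulation LS factors and
  multi-raster threat weighting are out of scope by design.
* Default biophysical parameters are synthetic placeholders in plausible
  ranges — usable for method studies, meaningless for any real region.
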