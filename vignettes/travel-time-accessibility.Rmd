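---
title: "Modelling travel time to healthcare on raster friction surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling travel time to healthcare on raster friction surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoaccess)
```

## The problem

Physical distance to care is one of the main barriers to accessing
healthcare in sub-Saharan Africa, and it matters most for older adults, who
are both more likely to need hospital-based care and less mobile. The
quantity of interest is the *travel time* from every inhabited square
kilometre to the nearest healthcare facility — separately for hospitals and
for facilities of any type — and the population-weighted distribution of
that travel time for adults aged 60 years and older.

`geoaccess` implements this analysis as a reusable pipeline:

1. build a **friction (impedance) surface**: a raster whose cells carry a
   traversal speed derived from land cover, the road network and water
   barriers;
2. compute **least-cost travel time** from every cell to the nearest
   facility with an exact multi-source Dijkstra over the 8-connected raster
   graph;
3. aggregate to the population grid and compute **population-weighted
   summaries**: cut-off category shares with Wilson score intervals,
   worst-quintile median/IQR, facility densities per 100,000.

A seeded synthetic-landscape generator replaces the external data sources
(gridded population projections, OSM extracts, master facility lists) so
that every stage runs — and is tested — offline.

## The cost model

Each 100 m cell carries a speed $v$ in km/h:

| class                     | speed    |
|---------------------------|----------|
| motorway / primary road   | 100 km/h |
| secondary road            | 50 km/h  |
| tertiary road             | 30 km/h  |
| barren land               | 5 km/h (walking) |
| built-up area             | 5 km/h (walking) |
| forest                    | 2 km/h (walking) |
| open water / rivers       | barrier (no travel) |

A cell crossed by a road takes the road's speed; where several road classes
cross one cell the fastest wins. Roads override land cover *including
water*: a road crossing a water cell models a bridge or causeway. Water
without a road is an absolute barrier, excluded from the path graph
entirely — unreachable cells are reported with a distinct sentinel
(`Inf`), never a large finite number, and count in the top open-ended
category of every summary.

Travel time between two adjacent cells $a,b$ is

$$ t(a,b) \;=\; d(a,b)\,\tfrac12\!\left(\tfrac{1}{v_a}+\tfrac{1}{v_b}\right), $$

with $d$ the cell size for axis moves and $\sqrt2$ times the cell size for
diagonal moves: time accrues half in each cell at that cell's own speed.
The per-cell minimum travel time to the nearest facility is the exact
multi-source Dijkstra solution over this graph (no approximation); the
priority queue breaks ties on (time, row, column) so results are bit-stable
across runs. Two conventions here are genuinely open — the neighbourhood
and the edge-cost convention are not dictated by the cost-distance idea
itself — and are fixed as: 8-connectivity with the $\sqrt2$ diagonal
metric, and the half-pace edge cost above, because they are the standard
raster cost-distance choices; destination-cell-only costing was considered
and rejected as it makes edge costs asymmetric for no modelling gain.

Travel times computed at 100 m resolution are aggregated to the 1 km
population grid as the **mean over finite** sub-cell values (configurable
to `min` or `median`; the aggregation statistic is a genuine free choice —
"aggregated" alone does not determine it). A 1 km block with no finite
sub-cell is unreachable; a fully-nodata block stays nodata.

National or regional borders never clip the path graph: people are assumed
to cross borders freely, with no time penalty. Region polygons are used
only afterwards, to attribute 1 km cells (by cell centre) and facilities
(by point-in-polygon) to reporting regions.

An optional slope correction (Tobler-style exponential decay of walking
speed in the slope magnitude, normalised to 1 on flat terrain) can be
applied to walking cells. It is off by default and documented as an
extension: the base analysis uses elevation only implicitly, through land
cover, because no slope formula is part of the core model.

## Facility registries

Facilities come from two registries: crowd-sourced OSM records (tag values
`hospital`, `clinic`, `doctors`) and a master facility list (MFL) style
inventory whose primary-care designations (`health_centre`, `health_post`,
`dispensary`, ...) are mapped to the primary-care class; only `hospital`
classifies as a hospital. The two registries are pooled **without
deduplication**: both are more likely to miss real facilities than to list
fictitious ones, and nearest-facility travel time is unaffected by exact
duplicates. A diagnostic (`countCrossSourcePairs`) reports how many
cross-registry pairs lie within a radius, but never alters the analysis
set. Facility density per 100,000 population is `1e5 * count / population`;
the packaged reference table (44 countries, both registries, primary /
hospital / total) exercises this arithmetic end to end.

## Statistical summaries

* **Cut-off categories.** Hospital travel time: `<2h, 2–6h, 6–12h, >12h`
  (boundaries 120/360/720 min). Any facility: `<1h, 1–2h, 2–6h, >6h`
  (60/120/360 min). Categories are closed-left: exactly 120 minutes falls
  in the 2–6 h class. Categorical maps are restricted to *populated areas*,
  defined as 1 km cells with at least one adult aged 60+.
* **Proportions.** The share of the 60+ population above a cut-off is the
  population-weighted share of 1 km cells with travel time beyond it;
  unreachable cells are above every cut-off. Wilson score intervals are
  attached. The effective denominator $n$ behind such an interval is a
  *reporting policy*, not a property of the rasters — population counts
  would make the intervals vanishingly narrow — so `n` is an explicit
  parameter, defaulting to the number of populated 1 km cells in the
  region. Published interval widths from comparable analyses are therefore
  not reproduction targets of this package.
* **Worst quintile.** Cells are sorted by travel time; the top fifth of the
  *population-weighted* distribution is taken, splitting the boundary
  cell's weight so the band holds exactly 20% of the population. Its
  weighted median and 25th/75th percentiles use the midpoint
  cumulative-weight rule (observation $i$ at plotting position
  $(\mathrm{cum}w_i - w_i/2)/W$, linear interpolation between positions,
  clamped at the extremes). Unreachable cells sit at $+\infty$ at the top
  of the ordering by default; if they dominate the band the statistic is
  reported as unreachable rather than silently dropped.
* **Histograms.** Population-weighted, closed-left/open-right bins, with a
  final open-ended bin holding the unreachable population, so the histogram
  mass always equals the regional population.

## The synthetic landscape

The generator emulates the *structure* the analysis is sensitive to, not
any particular country:

* settlements: `nSettlements` centres placed uniformly in the interior;
* population: isotropic Gaussian kernels (scale `settlementSpread`, default
  3 km) around settlements, mild lognormal noise, zero mass on water, and
  exact normalisation to `totalPopulation` (default 50,000 over a 30 × 30
  km default landscape, i.e. a rural density of roughly 50–60 adults 60+
  per populated km²);
* roads: the edges of the Euclidean minimum spanning tree over the
  settlements — the sparsest connected network, which makes road effects
  visible; longer edges get faster classes;
* land cover: barren background, contiguous water and forest blobs grown by
  seeded random dilation to the requested fractions (defaults 10% water,
  20% forest), built-up cores (~300 m) at settlements;
* facilities: placed near settlements off water, per-registry counts as
  requested (defaults: 18 MFL, 11 OSM, 7 hospitals in total), and a
  `duplicateFraction` (default 0.25) of MFL records re-listed in the OSM
  registry with ~30 m jitter, emulating partially overlapping registries.

All randomness derives from one integer seed through fixed per-generator
sub-streams, and every generator restores the caller's RNG state, so
generation is a pure function of (scenario, grid).

What the synthetic world does **not** emulate: dasymetric population
disaggregation (kernels stand in for it), realistic road topology beyond a
spanning tree, border geometries, facility geocoding error beyond the
duplication jitter, or any country's actual facility density. Passing
tests on synthetic data therefore validate the *computations* — cost
distance, aggregation, weighting, intervals — not any national estimate.

## Numerical choices and degenerate inputs

* Unreachable = `Inf` everywhere in memory; written to disk as `-1` in
  ASCII grids (restored on read); nodata uses the grid's nodata value.
* Facilities landing on a barrier cell are snapped to the nearest
  traversable cell within 10 cells (Euclidean on cell centres, ties by
  row then column), else dropped with a warning; an all-dropped set is an
  error, as is an empty one.
* An all-barrier landscape is legal input to the friction stage and yields
  an all-unreachable travel-time raster; population or facility generation
  on an all-water landscape is an error.
* Zero regional population is an error for proportions and quantiles
  (there is nothing to weight).
* The Wilson interval is clamped to contain the point estimate, guarding
  the closed-form containment property against floating-point rounding at
  the extremes.
* Summary CSVs are written with fixed column order and 12-significant-digit
  formatting, so identical configurations produce byte-identical files.

## Problem sizes

The test-suite and the bundled acceptance script run the full pipeline on
landscapes between 100 × 100 and 500 × 500 model cells (1–25 km² at 100 m
resolution scaled down from continental extents), with oracle comparisons
of the Dijkstra core on ~100 random grids up to 50 × 50. These sizes give
every code path — barriers, bridges, unreachable pockets, multi-source
competition — while keeping a full run in seconds.

## A worked run

```{r}
cfg <- pipelineConfig(scenario = syntheticScenario(seed = 1),
                      nRows = 100, nCols = 100, outDir = tempfile())
res <- runPipeline(cfg)
summaryTable(res$summaryHospital)[, c("total_pop", "p_above_cutoff",
                                      "ci_low", "ci_high", "q5_median_min")]
```

## Known limitations

Travel speeds are assigned, not measured; there is no time-of-day or
seasonal variation, no public-transport frequency, and the walking/driving
mix is implicit in the speed table. The model is isotropic (no slope sign)
unless the optional slope correction is enabled, and that correction is an
extension, not part of the base model. Registry pooling without
deduplication can only *under*estimate travel time when the same facility
appears in both registries at different coordinates. Facility readiness
and quality of care are outside the model entirely.
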