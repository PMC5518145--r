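---
title: "Gridded-population PSU sampling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gridded-population PSU sampling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpsu)
```

## The problem

Two-stage cluster household surveys (DHS/MICS/LSMS-style) first sample
communities — primary sampling units, PSUs — with probability proportionate
to population, then sample households within them. The usual frame, census
enumeration areas, fails where the census is outdated or inaccurate.
`gridpsu` substitutes a gridded population raster for the census frame:
every grid cell carries an estimated population, and PSUs are assembled
from cells. This vignette explains the model, every tunable parameter, the
numerical conventions, and what the synthetic tests do and do not
establish.

## The sampling model

**Frame.** Cells become frame records if their population is non-missing,
at least `cfg_min_pop_per_cell` (persons; default 0, a value like 0.01
drops cells that almost surely contain nobody while keeping totals nearly
intact), and covered by a stratum. Eligible cells are ranked in serpentine
order: rows north→south, alternating scan direction so consecutive cells
are spatially adjacent. Systematic sampling along this order yields an
implicitly spatially stratified sample.

**Seed selection.** Per stratum, `n_k = ceiling(cfg_hh_per_stratum /
cfg_hh_per_urban)` seeds are drawn by systematic PPES: interval
`I = P / n_k`, offset `u = r * I` with a single random number
`r ∈ [0, 1)` shared by all strata, sampling points `u + j I`. Half-open
cumulative intervals make each point land in exactly one cell. A cell more
populous than `I` can absorb several points; extra hits advance to the next
unselected cell in serpentine order (wrapping within the stratum), keeping
seed counts exact and seeds distinct. For cells with `p_i ≤ I` the
inclusion probability is exactly `n_k p_i / P`, which is what makes the
`(G_k/g_ik)/n_k` weight Horvitz–Thompson consistent.

**Sub-domain oversampling** (`cfg_sample_rururb`). Urban and rural
populations are sub-domains, not strata: each must yield at least
`cfg_hh_per_stratum` sampled households study-wide (seeds × households per
PSU of that class). While one falls short, the first non-seed cell of the
deficient class in serpentine order — from any stratum — replaces a
randomly chosen opposite-class seed of its own stratum. Interpreting the
minimum study-wide (not per stratum) follows from candidates being drawn
"from any strata"; each swap raises the deficient count by one, so the loop
terminates or reports infeasibility (e.g. a frame with no urban cells). If
both classes are somehow deficient, urban is corrected first — a documented
convention. The scan restarts at serpentine index 0 on each invocation.

**Spatial oversampling** (`cfg_sample_spatial`,
`cfg_sample_spatial_scale` in km). A coarse grid of side `scale_km` is
anchored at the raster's north-west origin; the fine-cells-per-side is
`round(scale_km * 1000 / side_m)` (min 1), where `side_m` is the ground
side of the grid's *centroid* cell — the single representative size that
corrects for degree-based cells shrinking toward the poles. Each coarse
cell containing eligible population but no seed receives the first
serpentine frame cell inside it, paired with a random drop from the same
stratum and sub-domain. A seed that is its own coarse cell's only seed is
never dropped (that would only move the hole, risking oscillation); an
insertion with no valid drop is skipped with a warning rather than
failing. Fixed adjustment order: selection → sub-domain → spatial.

**Growth** (`cfg_psu_growth`, `cfg_pop_per_psu`, `cfg_max_psu_size`).
Eligible cells are first partitioned into per-seed Voronoi regions —
nearest seed of the cell's own stratum by planar cell-centre distance, ties
to the lower PSU id — so PSUs can never overlap or cross strata. Growth
proceeds in round-robin passes over PSU id; each unfinished PSU adds one
cell drawn uniformly at random from the 4-neighbour frontier of its whole
member set (the natural dilation-filter generalization of choosing among
the seed's N/E/S/W neighbours), restricted to its region. A PSU stops at
`psu_pop ≥ cfg_pop_per_psu` (typical surveys use 400–600 people; overshoot
is bounded by one cell's population), at `area ≥ cfg_max_psu_size` km²
(area = member count × centroid-cell area; the parameter is an area even
though one usage note elsewhere reads like a side length — the km²
definition is implemented), or when its frontier is exhausted (flagged
`below_target`). With growth off, every PSU is its seed cell — the
configuration for one-stage or random-household designs.

**Outputs.** One record per PSU: `PSUid`, `stratum`, `psu_pop`/`psu_u_pop`/
`psu_r_pop`, `psus_in_stratum`, `str_pop`/`str_u_pop`/`str_r_pop`,
`str_cells`, `xCent`/`yCent` (seed-cell centre — the recorded PSU
coordinate — in decimal degrees for geographic grids, raw map units
otherwise, flagged in the sidecar), `U_R`, and a polygon equal to the
dissolved union of member-cell squares (holes from ineligible cells
preserved). GeoJSON avoids the shapefile dialect's 10-character field-name
truncation; no binary GIS writer is available in this build, so shapefile
output is refused explicitly.

## Reproducibility

All randomness descends from one number: the PPES start `r` (drawn
uniformly on [0,1) unless `cfg_random_number` supplies it) also seeds the
stream used for swap victims and frontier choices, in a fixed call order.
The number is printed, written to the manifest and sidecar, and feeding it
back reproduces every output byte-for-byte — the property the
reproducibility acceptance test asserts on file checksums. Whether the
original design drew one start globally or one per stratum is not
documented; the global choice is deliberate, so a single recorded value
reproduces the whole sample.

## Urban classification by density

When no urban boundary layer exists, `classify_urban_by_density(grid, f)`
finds the largest observed positive cell value `v` such that cells with
value ≥ `v` hold at least fraction `f` of the total population, and labels
those cells urban (ties at the threshold are urban). This reproduces the
"densest cells holding X% of the population" construction used to make a
16% urban mask from a national population raster. The threshold is
monotone non-increasing in `f`.

## Synthetic data: what it emulates and what it does not

The fixture generator is first-class, tested code. It produces:

* **population surfaces** — `uniform` (constant, default 5 persons/cell, a
  plausible rural 100 m density), `gradient` (linear west→east ramp, for
  order statistics with a known answer), and `blobs` (a sparse Bernoulli
  rural background plus Gaussian settlement bumps, default 5 bumps peaking
  at 50 persons/cell — a stylized small-town landscape with genuine
  urban/rural contrast); optional missing-data holes;
* **strata** — an r × c rectangular block partition, ids row-major;
* **urban masks** — the density-threshold rule applied to the generated
  surface.

All generators are pure functions of a seeded spec, and fixtures are
written as real ASCII-grid files so the full I/O path is exercised. They
emulate the *structure* of real inputs (alignment, missingness, density
contrast, strata coverage), not their realism: no dasymetric modelling, no
spatial autocorrelation beyond the bumps, square metre-based cells rather
than degree cells. A green test therefore establishes algorithmic
correctness (inclusion probabilities, invariants, reproducibility), not
that any particular national raster is an accurate frame — frame accuracy
is a property of the input data, outside the package's control.

## Numerical choices

* Half-open cumulative intervals and half-open cell extents
  `[west, east) × [south, north)`; 0-based row/col, row 0 northmost.
* Rasterization assigns by cell-centre membership (first containing
  polygon wins), not area weighting — deterministic and resolution-honest.
* Aggregation (`cfg_desired_cell_size`) sums factor × factor blocks,
  treats missing as 0 inside partially valid blocks, keeps all-missing
  blocks missing, and retains partial edge blocks, so total population is
  conserved exactly.
* Voronoi distances are planar cell-centre distances; for degree grids at
  country scale the distortion is far smaller than a cell.
* ASCII-grid output uses 17 significant digits, making write/read
  round-trips bit-exact for doubles.
* Degenerate inputs fail loudly: empty strata, all-zero grids, infeasible
  sub-domain swaps, `n_k` exceeding a stratum's cell count.

## Known limitations

* Inputs must share one georeference; there is no reprojection. Convert
  GeoTIFF/shapefile inputs with standard GIS tooling (`gdal_translate -of
  AAIGrid`, `ogr2ogr -f GeoJSON`).
* Weights use final-PSU populations (`g_ik = psu_pop`); the alternative
  adaptive cell-level weight accounting for growth-path probabilities is an
  open research question and deliberately not implemented.
* Sub-domain feasibility requires some stratum to hold both a candidate
  cell and an opposite-class seed; pathological geographies can make the
  minimum unattainable, which is reported as an error, not approximated.
* The external replication (national WorldPop raster, 30 district strata,
  416 households/stratum, 26 per PSU, 610 people per PSU, 16% urban rule →
  threshold 11 persons/cell, ≈75 urban / 405 rural PSUs, median PSU
  population ≈612) needs the downloaded raster: convert it and the
  rasterized districts to `inst/extdata/rwanda/{population.asc,strata.asc}`
  and reinstall; the corresponding acceptance test then runs the full
  pipeline. Offline it fails with an explanatory message rather than
  skipping silently.
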