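---
title: "Ichnological suitability mapping: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ichnological suitability mapping: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichno)
```

## The model

`ichno` implements a palaeontological predictive model for trace fossils
(ichnofossils) on a crater-lake landscape. The premise is that ichnofossil
sites are not randomly distributed: their location is controlled by a small
set of environmental attributes — the *suitability factors* — that can be
scored from a photogeologic map and a digital elevation model. Each factor is
scored on an ordinal 1–4 scale (4 = most desirable condition) per mapped
geological unit:

* `L` — substrate suitability for **bioturbation**: loose (soft) substrates
  allow organisms to displace grains; deltaic units score high, pre-impact
  basement scores low.
* `H` — substrate suitability for **bioerosion**: lithified substrates
  (hardgrounds) can be bored; the scoring is roughly specular to `L`.
* `E` — energy regime: high-energy settings (channels, proximal delta) erode
  surface traces, so quiet distal settings score high.
* `S` — sedimentation rate: slow sedimentation gives organisms more time per
  unit of accumulated sediment to rework the substrate.
* `W` — water-table position, scored from elevation rather than from the unit:
  cells strictly below the maximum palaeolake shoreline score
  `high_score` (default 4), cells at or above it `low_score` (default 1).
* `K` — surficial cover: unconsolidated recent deposits (dunes, talus,
  regolith) conceal the bedrock and any ichnofossils in it; uncovered bedrock
  scores 4.

Per grid cell the factor scores are aggregated by weighted linear combination
with a cover penalty:

$$ N = \Big( \sum_i x_i w_i \Big) - (4 - k) $$

with factor scores $x_i$, non-negative weights $w_i$ summing to 1, and cover
score $k$. Because the weights sum to 1, the weighted sum stays on the 1–4
ordinal range; the penalty $(4-k)$ then subtracts up to 3 points under
complete cover. Aggregates are **never clamped**: the theoretical range is
$[-2, 4]$, and negative values are meaningful ("excellent palaeoenvironment,
invisible under cover"). Three weight profiles produce three predictive maps:
`A` (bioturbation, uses `L`), `B` (bioerosion, uses `H`), and `C`
(biostratification, which ignores substrate cohesiveness entirely — microbial
mats and stromatolites form on both soft and hard substrates).

### The two weight presets

The source tables for the model print two inconsistent weight sets for A and
B (they agree for C). Both are shipped as named presets in
`load_weight_profiles()`:

| preset | A | B | C |
|---|---|---|---|
| `equations` (default) | 0.4 L + 0.2 E + 0.3 S + 0.1 W | 0.4 H + 0.1 E + 0.3 S + 0.2 W | 0.1 E + 0.4 S + 0.5 W |
| `table5` | 0.5 L + 0.1 E + 0.2 S + 0.2 W | 0.5 H + 0.1 E + 0.2 S + 0.2 W | 0.1 E + 0.4 S + 0.5 W |

The `equations` preset is the default because those are the operational
formulas printed alongside the predictive maps. Which set produced the
published rasters is not stated, so the choice is exposed rather than decided
silently.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `shoreline_elevation` | −2200 | m | the extended shoreline threshold, which also captures the highest reaches of the inlet channel; the initial fill level (−2243 m) is a documented alternative |
| `threshold` | 3 | score | splits the top quarter from the bottom three quarters of the 1–4 range; comparison is inclusive (≥) |
| `connectivity` | 8 | — | diagonal adjacency keeps narrow diagonal corridors as one site |
| `min_cells` | 4 | cells | discards single-cell speckle that no survey would target |
| `top_n` | 10 | sites | length of the ranked strategy list |

Boundary conventions are fixed, not configurable: "below the shoreline" is
strict (a cell exactly at the shoreline scores low), the classification
threshold is inclusive, and a cell center exactly on a polygon edge belongs
to the polygon. One behaviour each, documented, deterministic.

## Numerical and geometric choices

* **Rasterization** assigns each cell the unit of the polygon containing its
  center, with boundary counted as inside (even-odd rule across rings, so
  holes are supported); where polygons overlap, the later feature wins,
  mirroring map drawing order. The point-on-edge tolerance is
  `1e-9 * cell_size` metres.
* **Nodata** (`NA`) propagates through every per-cell operation; a suitability
  cell is nodata iff any required input is nodata there. No infilling.
* **Grid**: all rasters in a run share the DEM's grid; the DEM is the only
  intrinsically gridded input, so it defines resolution and extent.
* Arithmetic is double precision throughout; the test-suite oracle
  comparisons are exact to 1e-12.
* **Region labelling** is an iterative flood fill scanning cells in row-major
  order, so region ids are deterministic and reproducible.
* **Site ranking** orders merged sites by the maximum of their per-profile
  mean suitability scores, breaking ties by larger area, then smaller site
  id. Overlapping regions from different profiles merge into one site whose
  memberships drive the recommendations: A → bioturbation, B → bioerosion,
  C → biostratification; any bioerosion recommendation implies `sampling`
  (microborings can fall below imaging resolution), bioturbation or
  biostratification alone imply `imaging`, mixtures `imaging+sampling`.

## The synthetic landscape generator

`generate_landscape()` emulates the *map structure* the pipeline consumes: a
complete bedrock tiling (exterior plains, four rim quadrants of basement
units, crater floor with a fractured margin band, a western delta fan split
into proximal and distal lobes, and an inlet channel crossing the rim), a
fraction of the scene under randomly placed surficial patches, and a
bowl-shaped DEM (smoothstep radial profile plus small Gaussian noise) that
straddles the shoreline. The default scene is a 120 × 120 grid of 40 m cells
— a 4.8 km crater landscape small enough that the full pipeline runs in
seconds but large enough to produce multi-region strategies.

Defaults are fixed study conditions, not dials: 2000 m crater radius, 400 m
rim, floor at −2450 m and rim crest at −2000 m around the −2200 m shoreline,
delta at azimuth 270° with 60° spread, 25% surficial cover, 3 m DEM noise.
The RNG is Mersenne-Twister with inversion normals, so identical
`(params, seed)` give bit-identical scenes across platforms and R versions,
and the generator restores the caller's RNG state.

What the generator does **not** emulate: real photogeologic map complexity
(digitised polygon irregularity, mapping uncertainty, unit intergradation),
HiRISE-scale texture, erosional delta remnants, or any correlation between
surficial-patch placement and wind regime. Passing tests on synthetic scenes
therefore demonstrate the correctness of the scoring pipeline, not the
geological fidelity of any particular map.

`worked_fixture()` ships a 6 × 6 scene whose per-cell A, B, C values were
enumerated once with the scalar brute-force oracle and frozen; it pins the
whole pipeline to hand-checkable arithmetic (e.g. a crater-floor cell below
the shoreline and uncovered must score exactly A = 4.0).

## Degenerate inputs and edge behaviour

* An empty or absent surficial map means uncovered bedrock: `K = 4`
  everywhere.
* A bedrock map containing a surficial unit name (or vice versa) is a hard
  error before any raster work — silent mis-scoring is worse than a failure.
* An all-false mask yields an empty region list and an empty (0-row)
  strategy table.
* Grid mismatches between rasters abort naming the offending layer.
* On any stage failure `run_pipeline()` removes partial outputs, so an output
  directory is either complete (with manifest) or absent.

## Problem sizes

The shipped tests run the full pipeline on 60 × 60 and 120 × 120 synthetic
scenes and compare oracles on 20 × 20 fixtures; these sizes make the whole
suite complete in well under a minute while exercising every code path. The
pipeline itself is O(cells × features) in rasterization and O(cells) in every
raster stage, and has been run comfortably at several hundred cells per side.

## Known limitations

* The model is a relative ranking instrument: scores order locations within
  one study area and say nothing absolute about the existence of fossils.
* Expert steps of the original workflow — selecting factors and deriving the
  unit scores and weights — enter the package as configurable data
  (`load_catalogue()`, `load_weight_profiles()`), not as computation.
* No reprojection: all inputs must share one CRS, carried as an opaque token.
* Site extraction formalizes what was originally a manual map-reading step;
  its defaults (connectivity, minimum size, list length) are declared
  conventions, not values inferred from the source maps.
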