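---
title: "Mapping processes that govern the environmental fate of agricultural pesticides"
author: "pestfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping processes that govern pesticide fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestfate)
```

## The problem

Where agricultural pesticides are sprayed, their residues move: they leach
toward groundwater, run off over the surface, travel with eroded sediment,
bind to soil, or volatilize.  When direct residue measurements are sparse —
as they are across most of Africa — the relative *vulnerability* of a
landscape to each of these processes can still be mapped from public
gridded covariates: soils, terrain, climate and land cover.  `pestfate`
implements such a pipeline: five process-vulnerability indices on a shared
raster grid, the terrain and hydrology derivatives they need, a
one-at-a-time sensitivity analysis, and a residue observation database for
confronting the maps with field data.

Each map expresses *relative spatial variation* in a process on a
dimensionless [0, 1] scale, not an absolute rate.  The indices are linear
by design: the covariate–process relationships are pesticide- and
site-specific, and without local calibration data a weighted sum is the
defensible choice.

## The grid model

A `RasterGrid` is one north-up band with an affine georeference and a
nodata mask.  Three rules are global:

* **Alignment is enforced, never repaired.**  Arithmetic between grids with
  different shape, cell size or origin is an error.  `resampleMean()`
  (block averaging to a coarser grid, as one would average fine products to
  a working resolution) exists as an explicit utility and is never invoked
  implicitly.
* **Nodata propagates as a union.**  Any operation with a nodata input
  pixel yields nodata there; nothing is imputed.
* **Normalization is min–max over the full valid extent** — the analogue of
  normalizing a continental map continent-wide.  A constant map normalizes
  to 0 (degenerate rule, documented in `normalizeMinMax()`).  Min–max is
  sensitive to outliers in heavy-tailed variables (e.g. CEC); a robust
  quantile variant would change the maps and is deliberately *not* the
  default.

Soil properties arrive on seven depth intervals spanning 0–200 cm and are
collapsed with `depthWeightedAverage()` (thickness-weighted mean).  Depth
aggregation precedes normalization.

Raster interchange uses the plain-text ESRI ASCII grid format
(`readAsciiGrid()` / `writeAsciiGrid()`), with the nodata tag honored in
both directions; monthly stacks are 12 numbered files.

## Terrain and hydrology

The runoff and sedimentation models need a drainage structure, derived
from a DEM:

* `fillPits()` raises closed depressions to their spill level
  (Planchon–Darboux iteration, eps = 0), so every cell has a non-ascending
  path to the grid edge; nodata holes act as drains.
* `d8Flow()` routes each cell to its steepest-descent neighbour (drop over
  distance, diagonals by √2).  Flats are drained by an epsilon gradient
  toward the filled-DEM spill path, and exact ties are broken by the fixed
  neighbour order E, SE, S, SW, W, NW, N, NE — determinism matters more
  than any particular tie choice.  Accumulation counts the cell itself, so
  it is at least 1 and its logarithm (for TWI) is defined everywhere.
* Slope uses Horn's 3×3 weights on the *unfilled* DEM (filling flattens
  real pits); borders use one-sided differences via linear extrapolation.
* TWI is `ln(a / tan β)` with the specific catchment area
  `a = accumulation × cell size` and `tan β` floored at 0.001 so flat
  pixels stay finite.
* `delineateWatersheds()` cuts the stream network (accumulation ≥ a
  threshold, default 50 cells — a free parameter, since the reference
  stream products cannot be reproduced from a synthetic DEM) into segments
  between confluences and labels every cell by the segment its flow path
  first reaches.  Cells whose path exits the grid without touching a
  stream are collected under an explicit label 0 ("unchanneled") so the
  labels still partition the valid extent.  Segment stream length is the
  sum of flow steps including the outflow step, floored at one cell length
  so a single-cell terminal reach has nonzero length (the Horton form
  factor divides by it).
* The Horton form factor ("catchment capacity") is area / stream length as
  used here, with the classical area / length² available behind the
  `horton` dialect flag — the two circulate side by side in the
  literature and differ only in scale for the normalized indicator.

## The five process models

**Leaching** is a DRASTIC-weighted index over normalized inputs:

  L = 5·D + 5·(1 − GW) + 2·(1 − DB) + (1 − SL) + 5·SM

with drainage-class score D, groundwater depth GW, depth to bedrock DB,
slope SL and mean soil moisture SM; L is then min–max normalized.  The
three-level infiltration vocabulary (low < 15 mm/h, moderate 15–50 mm/h,
high > 50 mm/h) has no canonical numeric coding; equally spaced scores
{0, 0.5, 1} are the default and are configurable.  The drainage-class
layer doubles as the bedrock-porosity indicator, so no separate bedrock
input exists.  Depths and slope are normalized first and complemented
inside the index, as written.  Cracked-clay (Vertisol) infiltration is not
modelled.

**Surface runoff** follows the IRIP idea — susceptibility scores for
runoff *generation*, *transfer* and *accumulation* built by combining
simple per-pixel indicators — with continuous normalized indicators in
place of the classical binary ones.  The combination is the arithmetic
mean, which is the sum of binary indicators up to scale: on {0, 1} inputs
the continuous score times the indicator count equals the classical
integer score exactly (a tested identity).  Orientations: impermeable and
thin soils *generate* runoff (drainage and thickness complemented); steep
slopes *transfer* it but flat terrain *accumulates* it (slope complemented
in the accumulation stage only); a compact catchment (higher form factor)
transfers more.  Break of slope and artificial linear axes are not
representable at a coarse continental grid and are omitted.  A 17-class
land-cover product is regrouped to the five weight classes (Forest 0,
Grass/scrub/woodland 0.2, Barren 0.6, Cultivated 0.8, Built-up 1) via an
editable YAML table.

**Sedimentation** combines USLE erosion with watershed hydraulics.
Erosion is `E = R·K·C·S` (t/ha/yr): rainfall erosivity R; erodibility K
from the Wischmeier–Smith nomograph

  K = [2.1×10⁻⁴·M^1.14·(12 − OM) + 3.25·(s − 2) + 2.5·(p − 3)]/100 × 0.1317

with the textural factor `M = (m_silt + m_vfs)(100 − m_clay)` and
`m_vfs = 0.2 × m_sand`; C = 1 − EVI (vegetation shields the soil); and the
slope-steepness factor S with its branch at a 9 % slope (tested on tan θ):
`10.8 sin θ + 0.03` below, `16.8 sin θ − 0.5` at or above (the jump at the
breakpoint is ≈ 0.008).  Slope *length* acts at much finer resolution than
the working grid and is excluded, as is the support-practice factor P (no
spatial data).  K is floored at 0 — the nomograph can go negative for
extreme inputs.  The `eq4_form` dialect flag also offers the
parenthesization `m_silt + m_vfs·(100 − m_clay)` that circulates in some
transcriptions of the nomograph; the standard form is the default.

Sediment load per watershed is the sum of erosion over its cells.  Stream
velocity on stream cells follows the slope–area scaling

  V = V_m · s^b A^c / [s^b A^c]_m ,  b = c = 0.5

where [·]_m is the watershed mean over stream cells (velocity is evaluated
on streams only — deposition happens in channels), slope is floored at
10⁻⁴, and the watershed velocity scale V_m is taken as the watershed mean
of the normalized slope (only "related to mean slope" is specified by the
method; the choice is injectable).  The watershed mean of V equals V_m by
construction — a tested identity.  The final index is
`normalized load × (1 − normalized velocity)`, renormalized: deposition is
favoured where much sediment moves slowly.  For the full-extent map,
off-stream cells carry their watershed's velocity scale.

**Soil storage and filtering capacity** is the unweighted sum
`SFC = OC + clay + (1 − pH) + CEC` over normalized, depth-aggregated
inputs, normalized to [0, 1].  Low SFC marks soils that retain little —
more of an applied pesticide stays mobile.  Pesticide-specific sorption
(charge, half-life) is out of scope.

**Volatilization** is a monthly index
`V_i = WV_i + Srad_i + T_i + PET + (1 − RH_i)` over normalized wind,
radiation, temperature and humidity stacks, with the annual-only PET layer
entering every month identically.  Monthly stacks are normalized *across
the whole 12-band stack*, not per month, so months remain comparable.  The
pipeline reports the annual mean (normalized) and the population standard
deviation of the 12 monthly values (divisor 12: the year is the complete
cycle, not a sample), which is exactly 0 where the seasonal cycle is
constant.

## Sensitivity analysis

`oatVariable()` scales one raw input by (1 + δ) (default ±5 %), re-runs
the full model, and reports the mean and SD over valid pixels of
100·|out′ − out| / out, excluding pixels whose baseline output is below
10⁻⁹ (percent change is pixel-relative; the dispersion is the pixel SD —
both choices made here, as the summary statistic is not otherwise pinned
down).  Two mechanics deserve note:

* **Normalization bounds are part of the fitted pipeline.**  Min–max
  normalization is affine-invariant, so recomputing the bounds after a
  pure rescaling would report exactly zero sensitivity for every
  normalized input.  The pipeline therefore rescales a perturbed input
  with its *baseline* bounds and clips into [0, 1]; the clipping is what
  makes the +δ and −δ responses asymmetric for variables that hug a bound.
  Purely linear positively oriented models (no renormalization) respond
  exactly symmetrically — 5 % for an identity model, 2.5 % for an equal
  two-term sum — which the tests assert to machine precision.
* **Weight deviations.**  `oatLeachingWeights()` shifts each leaching
  weight by ± d points (d = 1..4), one at a time, keeping only shifts that
  stay within the weights' 1–5 range — excluded shifts would otherwise be
  clamped to a smaller magnitude and break the near-proportionality of the
  response, which is a structural property of a linear index.  On
  synthetic inputs the mean response is proportional to d with a
  through-origin R² above 0.99.

The perturbed drainage score, an ordinal quantity already on [0, 1], is
clipped rather than renormalized.

## The synthetic scenario generator

Every pipeline input can be generated by `synthScenario()` from a
`ScenarioSpec`: kernel-smoothed Gaussian random fields rescaled to
realistic ranges (groundwater depth 0.5–80 m, pH 4.5–8.5, rainfall
erosivity 200–12000 MJ·mm·ha⁻¹·h⁻¹·yr⁻¹, ...), a ridged DEM (broad-scale
correlated surface + finer roughness + a gentle tilt, relief 400 m) whose
D8 network yields several watersheds on a 128×128 grid, categorical
drainage/structure/land-use classes cut from latent fields at set
proportions, monthly climate as base field + seasonal sinusoid + 10 %
noise, soil profiles on seven 0–200 cm intervals with depth trends
(organic carbon decays with depth), texture fractions from a softmax (sum
exactly 100 %), a shared contiguous nodata mask (2 % by default), and a
residue table with exact per-(compound, substrate) counts and a
controllable number of distinct sampling sites.

One master seed fans out to per-variable subseeds by stable string
hashing: adding a new generator never perturbs existing outputs, and every
artifact is bit-for-bit reproducible.  The emulation is *statistical*
(ranges, spatial autocorrelation, seasonality, class mixtures) — no
geographic realism is claimed.  Passing tests on synthetic data therefore
demonstrate the internal correctness of the pipeline (conservation laws,
identities, monotonicity, exact table lookups), not the fidelity of any
map to a real landscape: real covariates are coarser, crosscorrelated and
gappy in ways the generator does not reproduce.

Default problem sizes: unit tests run on 32–48² grids; the end-to-end
scenario and the acceptance script use the package default of 128×128
cells of 1 km — large enough for a few hundred stream segments, small
enough that the whole suite runs in seconds.

## Residue database

`readResidueCsv()` validates a residue table against the extraction
schema (study, year, months, substrate, collection method and depth,
extraction and quantification methods and limits, compound and class,
concentration, coordinates).  Hard violations (substrate outside {soil,
sediment, water, air}, negative concentration without a below-detection
flag) reject the *row* into a side table with a reason — never silently.
Coordinates outside the bounding box (default continental Africa, lat
−35..38, lon −26..64) leave the row accepted but non-georeferenced.
`residueFunnel()` reports totals, georeferenced counts, per-substrate
counts *among georeferenced observations* (they may sum to less than the
total), distinct compounds and studies, and — for a compound/substrate
selection — observations and unique locations, where unique means
distinct (lat, lon) pairs at full stored precision (a rounding option
exists, since "same location" is precision-dependent).

## Known limitations

* The indices are linear and uncalibrated; they rank, they do not
  predict.  The five maps are deliberately *not* combined into a single
  risk score — the weights such a combination needs do not exist yet.
* Min–max normalization ties every map to the extremes of its extent;
  clipping or robust scaling would change rankings near the tails.
* D8 routing concentrates flow into single-cell channels; dispersive
  (multiple-flow-direction) schemes would spread accumulation and lower
  TWI contrast.
* The stream threshold, the Horton dialect and the indicator orientations
  are configuration, not truth; results should be read conditional on
  them.
* Pesticide-specific behaviour (degradation, sorption chemistry,
  application dose and method) is out of scope throughout.
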