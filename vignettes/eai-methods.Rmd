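---
title: "Methods: the Environmental Area Index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Environmental Area Index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eairisk)
```

## The model

The package grades ecological risk from gridded environmental factors in
three steps. First, each raw factor raster is mapped through a fixed
lookup table to a score in (0, 10]: higher scores mean better
environmental quality (the altitude table is the one deliberate
exception — its scores fall as the ground rises, because high elevation
means harsher growing conditions).
Second, the scores are pooled into three quality indices by geometric
mean: climate (six factors, exponent 1/6), soil and vegetation (five
factors each, exponent 1/5). The geometric mean is the ESA-family
convention: it penalises a single very poor factor more than an
arithmetic mean would, encoding the idea that one failing resource limits
the whole system. Third, the indices combine linearly into the
Environmental Area Index,

EAI = w_c·CQI + w_s·SQI + w_v·VQI,  w = (0.6, 0.2, 0.2),

and **low EAI flags high risk**. The five risk classes run HeERA → PERA
(highest to lowest risk) with fixed breaks 2.66 / 3.66 / 4.86 / 6.18.

Two modelling ambiguities were resolved as package design choices:

* **The EAI equation.** The source formulation prints only a climate and
  a vegetation term, yet assigns three coefficients and constructs a soil
  index that would otherwise go unused. The package's default is the
  three-term convex combination above; the two-term variant
  (`form = "two_term"` in `compute_eai()`) is retained for comparison.
* **Slope.** The climate-quality narrative calls slope an auxiliary
  factor, but no slope score column exists and the index formula has no
  slope term; the package follows the formula (altitude only). Aspect
  *is* a scored vegetation factor, and `aspect_from_dem()` derives its
  four insolation classes from a DEM when no aspect raster is supplied.

## Interval and endpoint conventions

Published bins are printed as "a–b", "< a", "> b" without endpoint
ownership. The package applies one convention everywhere: **bins are
closed on the left and open on the right**, "< a" is (−∞, a), "> b" is
[b, ∞). The same rule applies to classification breaks (a value exactly
on a break belongs to the upper class) and to elevation bands. The soil
depth table prints four point values (0, 10, 30, 100 cm); it is
implemented as the step function [0,10) → 2.5, [10,30) → 5.0,
[30,100) → 7.5, [100,∞) → 10.0, which reproduces every printed pair
without inventing an interpolation. Scores are always members of the
printed score set — never interpolated. The vegetation-cover table's
upper bins (100–158, > 158) exceed 100 %; they are applied exactly as
printed on the raw variable, with a validation warning when inputs exceed
100, because correcting the table would un-anchor it from its source.
The minimum score across all sixteen tables is 1.25, so geometric means
are always defined and strictly positive.

## Classification

`classify_by_breaks()` applies fixed schemes; `jenks_breaks()` computes
exact Fisher–Jenks natural breaks by dynamic programming over the sorted
unique values with frequency weights — no sampling, hence deterministic
without a seed. Complexity is O(k·u²) in the number of distinct values u;
that is instant for series and moderate rasters but deliberate on rasters
with ~10⁵ distinct cells, which is why the pipeline's default
classification mode is the fixed published scheme. The fixed scheme is
also the default for future periods, so that period-over-period change
rates compare like with like; `jenks_per_period = TRUE` re-breaks each
period instead.

## Weight estimation

`estimate_weights()` reproduces the importance-screening procedure: a
random-forest classifier (bagged CART, gini splits, `mtry` features per
split, defaults `mtry = 2`, `ntree = 1000`) of a reference risk label on
(CQI, SQI, VQI). Mean-decrease-in-impurity importances, normalised to sum
to one, become the weights; out-of-bag accuracy is reported as the
goodness of the weighting. The forest is implemented in the package
(no forest package is assumed present) and is fully seeded. What the
original forest actually predicted is not documented at the source, so
the reference label is user-supplied;
`generate_weight_training_samples()` manufactures labels from a hidden
ground-truth EAI with configurable true weights, which is what the
recovery tests exercise. No attempt is made to reproduce the published
92.02 % goodness figure — it depends on training samples that were never
released.

## Trend statistics

`trend_rate()` is the OLS slope of value on calendar year × 10 (units per
decade) with the R² of that fit. Fits use annual regional means of the
ensemble mean rather than period means: annual fits use all the
information and make the closed-form slope standard error available to
the tests. A constant series reports rate 0 with R² 0 by convention.
Change rates between periods are percentage-point differences of
class-area shares per stratum, which is the only algebra under which each
stratum's changes sum exactly to zero. Area is cell count × cell area
with no latitude correction — the grid projection is opaque to the
package (a documented limitation).

## The synthetic world

`generate_base_scene()` states one fixed world rather than exposing
dials:

* a latent quality ramp rising **northwest → southeast** (row 1 is the
  northernmost row), shared by all quality factors so that risk falls
  toward the southeast;
* a DEM **highest in the northwest**, rank-mapped so the five elevation
  bands (< 2300, 2300–3600, 3600–4400, 4400–5000, > 5000 m) occupy the
  published area shares 1.97 / 16.11 / 21.52 / 37.75 / 22.65 %;
* per-factor spatially smoothed noise with sd 0.05 on the [0, 1] latent
  scale — enough to decorrelate factors and create mixed classes without
  drowning the gradient (no spatial covariance is documented at the
  source; a 3×3 moving-average kernel is the simplest coherent
  structure);
* aspect is spatially random: insolation has no reason to follow the
  quality gradient.

`generate_scenario_series()` adds linear trends at the published
per-decade rates (7.2 / 10.5 / 12.3 / 16.6 mm and 0.07 / 0.28 / 0.56 /
0.62 °C for SSP126/245/370/585), optionally patterned so precipitation
trends fastest in the southeast and warming fastest in the northwest.
(The source text contradicts itself on the warming pattern's direction;
the generator follows its discussion section: fastest warming in the
northwest.) Interannual variability enters as per-member *regional*
anomalies (defaults 25 mm, 0.4 °C — magnitudes a plateau climatologist
would call unremarkable for annual means); there is no fine-scale
spatially independent interannual noise, no GCM-like spatial modes, no
glacier or permafrost dynamics, and no vegetation feedback. The default
ensemble has 3 members (the nine named GCMs of the source are
generalised to "members"; three keeps a desktop run light). Only
precipitation and temperature evolve; soil factors are held fixed (the
source's own assumption), and drought index, accumulated temperature,
PAR and NPP default to static because no evolution rule for them is
documented.

A green end-to-end test therefore establishes that the *machinery* —
scoring, index algebra, classification, zonal accounting, trend
fitting — is correct on a world with the stated structure. It does not
establish anything about the real plateau: the published area
percentages require the real rasters and are out of scope here.

## Determinism and numerics

Every random stream derives from a master seed through a fixed
affine counter scheme reduced modulo a prime below 2³¹, so adding a factor
never perturbs the others and identical configs give byte-identical text
outputs (rasters are written with 17 significant digits; provenance
records contain no timestamps). Nodata is a mask, never a sentinel value
in arithmetic; every combination step takes the union of input masks.
Weight vectors must sum to 1 within 1e-9; geometric means refuse
non-positive scores (they can only arise from a corrupted table).

## Known limitations

* Raster I/O is plain-text ESRI ASCII grids; there is no GeoTIFF or CRS
  transformation support (the CRS tag is carried verbatim).
* Exact Jenks on very large unique-value sets is O(k·u²).
* Cell areas are treated as equal; unprojected lat/lon grids would need
  external latitude weighting.
* The synthetic world is a testbed, not an emulator of any real region.
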