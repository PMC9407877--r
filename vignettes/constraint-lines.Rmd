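---
title: "Constraint lines between ecosystem services: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint lines between ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eslines)
```

This vignette records how the package models its science, which defaults
were genuinely open choices, what the synthetic-data generator does and
does not emulate, and the numerical conventions a maintainer should know.
It states no empirical result that the test suite or the acceptance
script does not itself compute.

## 1. The constraint-line model

For a pair of services written `A_B`, `A` is the constraining service on
the x-axis and `B` the response. The working assumption is that the
*upper envelope* of the (A, B) pixel cloud is a smooth function `f`
reflecting the maximum `B` attainable at each level of `A`; pixels below
the envelope are pushed down by other limiting factors. Two envelope
families are supported:

- **hump**: a concave quadratic. Its vertex is the *threshold*
  `(threshold_x, threshold_y)`; the sign of the constraint's trend flips
  there. A fit with non-negative curvature is rejected as a form
  mismatch rather than reported with a meaningless vertex, including the
  degenerate flat case `|a2| <= 1e-12`.
- **exponential**: `y = b k^x`, fitted by regressing `ln y` on `x`.
  `b = f(0)` is the bound when the constraining service is almost absent;
  `k` is the per-unit decay base, so values just below 1 (e.g. 0.9995 per
  unit of a service spanning thousands of units) still describe a strong
  cumulative constraint.

### Boundary extraction (quantile segmentation)

`extract_boundary()` splits the observed x-range into `n_bins`
equal-width bins and keeps, for each bin holding at least `min_points`
observations, the point `(bin centre, Q_q(y))`. Defaults — 50 bins, `q =
0.99`, `min_points = 10` — follow the quantile-segmentation literature;
the source study does not state its settings, so all three are config
keys and every pipeline output embeds the configuration used. Sparse bins
are dropped and counted, and fewer than five surviving bins aborts the
fit rather than extrapolating. All empirical quantiles in the package
(boundary extraction and box statistics alike) use the linear
interpolation (type-7) rule, for internal consistency.

R² is computed on the boundary points, on the original y scale, for both
forms. Whether the study computed its goodness of fit on boundary points
or the full cloud is unstated; boundary points are the fitted data, so
they are the defensible choice, and the alternative would only lower R².
Likewise, thresholds are taken from the fitted vertex, not the maximal
boundary point: the vertex uses all boundary points and is robust to a
single noisy bin.

### Sampling

`run_pairs()` samples up to `sample_n` (default 10,000) co-located valid
cells per pair and year, with a seed derived from the global seed, rather
than using every pixel; a desk-scale grid rarely has more anyway, and the
estimator is a quantile, which stabilizes quickly. Pairs involving food
production are evaluated on cropland cells only, since FP is defined only
there.

## 2. The four service models

**NPP (CASA).** The source gives only `NPP = APAR x eps` per month and
defers the closure to its references, so the package uses the standard
one: `APAR = SOL x FPAR x 0.5`, FPAR linear in NDVI between `ndvi_min`
and `ndvi_max` (capped at `fpar_max`), and `eps = eps_max(class) x
T-stress x W-stress`. The stress terms deliberately avoid solar
radiation: temperature stress is a Gaussian around `t_opt` and water
stress uses a temperature-proportional monthly PET proxy, which keeps
NPP exactly linear in SOL at fixed efficiency — a property the tests
exploit. Monthly NDVI comes from the annual surface via fixed phenology
weights (mean 1, summer-peaked). Internal units are g C m⁻²; output is
t ha⁻¹ (x 0.01). Water and urban cells are fixed at zero.

**FP.** Within each administrative zone the reported total yield is
allocated to cropland cells proportionally to NDVI, so the zone sum is
conserved exactly — the invariant the tests check to 1e-6 relative. A
zone with no positive cropland NDVI is skipped with a warning, never
silently zeroed into the denominator.

**SC (RUSLE).** `SC = R K LS (1 - C P)`, the difference between
potential and actual erosion. The factor closures (the study's appendix
is not available) are the most widely used ones: monthly Wischmeier
erosivity for R; the EPIC texture/organic-carbon formula (SI conversion
0.1317) for K; D8 slope with the two-piece McCool steepness relation and
`(lambda/22.13)^m` length factor for LS; `C = exp(ln(c_floor) x fc)`
decaying from 1 at bare soil to `c_floor` (default 0.01) at full
fractional cover; P by class lookup with water/urban at 0. All constants
sit in `rusle_params()` and are flagged as replaceable.

**WY (Budyko–Fu).** `WY = (1 - AET/PPT) x PPT` with
`AET/PPT = 1 + r - (1 + r^w)^(1/w)`, `r = PET/PPT`,
`w = AWC x Z / PPT + 1.25`. The printed layout of the source equation is
ambiguous; this is the InVEST definition it cites. `Z` defaults to 7.5 —
the source never states its value — and is a config scalar. The
`(1 + r^w)^(1/w)` term is evaluated in log space so extreme `w` neither
under- nor overflows, which is what makes the analytic limits (`PET -> 0
=> WY = PPT`; `w -> inf, r < 1 => WY = PPT - PET`) hold to 1e-6 in the
tests. Cells with zero precipitation return 0 by convention (synthetic
grids may contain arid cells) with a logged count.

## 3. Landscape metrics

Patches are maximal connected components under 8-connectivity by default
(the FRAGSTATS default; configurable, and recorded in the output).
Perimeters and total edge include the landscape boundary; adjacency
counts for CONTAG exclude it and use the double-count convention. PAFRAC
is `2 / slope` of the OLS regression of ln(area) on ln(perimeter) and
requires at least 10 patches — below that it is reported as `NA`, never
silently 0.

One property worth recording: CONTAG measures the *predictability* of
cell adjacencies, not aggregation per se. For two classes, a perfect
checkerboard concentrates the adjacency distribution on the two
off-diagonal entries and scores exactly 50%, while two solid halves
approach 50% from below (the seam adds entropy). The tests therefore pin
the checkerboard at its closed-form 50% and check aggregation
monotonicity with a clumped-vs-random contrast at fixed composition,
where the intuition does hold.

## 4. Characteristic-value dynamics

Trends are OLS of value on calendar year with a two-sided t-test — the
source reports slopes with significance stars but never names a test, so
the simplest defensible one is used (a Mann–Kendall alternative would be
a natural extension but is not the default). Stars follow the usual
convention: `**` for p < 0.01, `*` for 0.01 <= p < 0.05. A constant
series returns slope 0 with p = 1 and an explicit flag. Box statistics
use type-7 quartiles with 1.5 IQR fences; type 7 is the convention that
reproduces the printed 4.29–5.06 quartile range of the packaged
characteristic table exactly, which is why it is fixed package-wide.

The 21-year characteristic-value table ships as a plain-CSV fixture
(`load_table4()`) so the worked acceptance targets run without the full
pipeline. Two transcription notes: the sub-column printed under NPP_WY
with the header "FP" holds NPP thresholds and is labelled
`npp_threshold`; and the prose states a 2003 minimum of 5.35 for the
WY_FP FP threshold where the table prints 5.25 — the fixture preserves
the table value and the discrepancy is documented, not resolved. The
table also prints the year 2000 twice; the second occurrence is read as
2001.

## 5. Driver attribution

The original analysis used SPSS "automatic linear modelling", which is
proprietary; the stand-in is fully documented and makes no claim of
bit-compatibility. Response and drivers are standardized (mean 0, sd 1;
near-constant or partially undefined columns are dropped with a log
message); selection is forward stepwise by AICc with a VIF cap (default
10) as collinearity guard; a retained-term cap (default 6) keeps 21
annual observations from being overfitted. Relative importance is the
LMG decomposition — sequential R² increments averaged over all orderings,
computed exactly from all-subset R² values, then normalized to sum to 1,
matching the "total relative importance is 1" property the source
states. Accuracy is adjusted R² x 100, floored at 0. Model 1 adds the
ten products of {GDP, population} x {PAFRAC, LSI, CONTAG, SHDI, PD},
computed on standardized columns and re-standardized.

The one genuinely consequential choice is the **entry threshold**. A
flat "AICc must improve by 2" rule ignores that the best of ~25
candidates is selected, and selection-of-the-maximum inflates the
apparent gain; in simulation it admitted spurious interactions far more
often than the 10% budget the recovery criteria allow. The default is
therefore the multiplicity-adjusted margin `2 ln(p)` for `p` candidates
(the risk-inflation criterion), with an explicit numeric `aicc_margin`
as override. True signals of the strength the recovery tests posit clear
either threshold by an order of magnitude. A second guard stops
selection when the residual sum of squares is at machine-epsilon scale,
where AICc comparisons are meaningless — this is also what enforces "a
perfectly explained Model 0 admits no interaction".

## 6. What the synthetic generator does and does not emulate

The generator's defaults describe a cropland-dominated plain: 62%
cropland with a slow conversion to urban land, ~700 mm precipitation
with a weak positive trend and 70% of the annual total in June–August,
NDVI positively coupled to precipitation, relief concentrated in a
central mountain so the LS factor has contrast, and zone yields around
3.5 t ha⁻¹ growing a few percent per year. Land-use mosaics come from a
modified-random-clusters scheme: class nuclei (fewer as `clumping`
rises) grown outward under per-class quotas, which makes realized
composition exact to one cell while leaving configuration metrics
responsive to the clumping knob. Climate anomaly fields are smoothed
white noise rescaled to unit variance *without* removing the grid mean:
smooth fields have few effective degrees of freedom, so their spatial
mean fluctuates year to year, which is what gives the driver matrix
honest interannual variance around the configured trend paths.

Scatter clouds with a known envelope use multiplicative uniform-power
noise, `y = f(x) U^gamma`: every point is below `f` by construction and
`gamma` controls how densely the boundary is populated. This reproduces
the geometry the method assumes — which is exactly why a green recovery
test establishes *estimator correctness*, not the ecological claim that
real service pairs have such envelopes. Similarly, the generator imposes
no causal pathway from land-use pattern to the service layers beyond the
mechanistic models themselves, so attribution tests demonstrate that the
selection machinery finds signals planted in the driver matrix, not that
the synthetic landscape reproduces the source region's driver rankings.
Reproducing the study's regional numbers (its mean water yield, its
specific R² and contribution tables) would require its real rasters and
is explicitly out of scope.

## 7. Numerical conventions and degenerate inputs

- Rasters are row-major matrices, origin top-left; areas always come
  from `cell_size`, never a projection. Text I/O is ESRI ASCII grid;
  configs and manifests are JSON.
- All generators are pure functions of (parameters, seed); the pipeline
  derives per-stage seeds from the global one, and re-running a config
  reproduces every CSV byte for byte.
- Degenerate inputs have defined behaviour rather than accidents: a flat
  DEM yields the minimum LS (logged); zero-precipitation cells yield
  WY = 0 (logged); a zone without cropland NDVI is skipped with a
  warning; an all-constant trend series returns p = 1; undefined metrics
  (CONTAG with one class, PAFRAC under 10 patches) are `NA` markers.
- `sample()`'s scalar-first-argument behaviour is never relied on; an
  internal `resample()` guards every length-1 draw.

## 8. Known limitations

- RUSLE is cell-local: no flow accumulation or sediment routing, and the
  slope-length is approximated by the cell size.
- The FP model inherits the source's assumption that yield scales with
  NDVI within a zone; the synthetic yield tables are consistent with it
  by construction.
- Landscape metrics are landscape-level only (the five configuration
  metrics plus composition); there is no class-level suite or moving
  window.
- The attribution stand-in mimics the *shape* of automatic linear
  modelling outputs (standardized coefficients, stars, importances
  summing to 1, accuracy %) but not SPSS internals, which are
  undocumented.
- With 21 observations and ~25 candidate terms, any selection procedure
  has limited power; the conservative entry threshold trades a little
  power for a controlled false-entry rate, and that trade-off is the
  package's position, not a fitted constant.
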