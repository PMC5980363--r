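---
title: "Ensemble niche modeling for climate-change range forecasts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`enmpipe` implements a complete ensemble environmental-niche-modeling (ENM,
also called species distribution modeling) workflow of the kind used to
forecast climate-driven range shifts for mountain ungulates: occurrence
points plus gridded environmental layers in, consensus habitat maps and
stable/gain/loss change accounting out. This vignette explains the models
and procedures, the tunable parameters and their defaults, what the
synthetic landscape generator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## The modeling protocol

The pipeline runs in three stages.

**1. Data preparation.** Raw presence points are thinned to one per raster
cell (clustered sightings otherwise bias the spatial sample), then split
70/30 into training and testing subsets by uniform seeded sampling; the
training size is `floor(0.7 n)`. Pseudo-absences ("background" points,
default 10,000) are drawn uniformly inside the 95% minimum convex polygon
(MCP) of the presences, restricted to cells where every predictor is valid.
The 95% MCP keeps the `ceil(0.95 n)` presences closest to the presence
centroid (Euclidean distance in degrees) and takes their convex hull; the
trimming rule is exposed in configuration because no single convention
exists. Predictor values are extracted at each point by cell lookup, and
collinear predictors are pruned: pairs with Pearson `|r| > 0.7` (strict
inequality, with a 1e-10 epsilon so a correlation numerically equal to the
threshold survives) are visited in decreasing `|r|` and the lower-priority
member of each still-retained pair is dropped. Priority is an explicit
ranked list — a reproducible stand-in for the literature-based expert choice
practitioners use — defaulting to the bioclim variables most implicated in
mountain-ungulate habitat (annual mean temperature first), then terrain
ruggedness and the remaining topographic predictors.

**2. Present-day models.** Five presence/background families are fitted
behind one contract (`fit_model`/`predict` with suitabilities in [0, 1]):

- `glm_stepwise` — logistic regression with bidirectional AIC stepwise
  covariate selection;
- `mars` — additive multivariate adaptive regression splines, written for
  this package: forward selection of reflected hinge pairs (15 candidate
  knots per predictor at quantiles), generalized-cross-validation backward
  pruning (penalty 2), then a logistic refit on the surviving basis;
- `brt` — stagewise gradient-boosted trees (xgboost), learning rate 0.01,
  depth 3, up to 2,000 trees with the count chosen by 10-fold
  cross-validated log-loss — the Elith-style defaults for ecological BRTs;
- `rf` — 500 bootstrap-aggregated classification trees with balanced
  (down-sampled) class strata per tree, the standard remedy for
  presence/background imbalance; suitability is the class-1 vote fraction;
- `maxent_like` — a Maxent-style model through its penalized-logistic
  equivalence: lasso logistic regression (glmnet) on a linear + quadratic +
  reflected-hinge feature expansion (8 knots per predictor), with the
  penalty chosen by cross-validation. Implementing the equivalence rather
  than wrapping the Java application keeps the pipeline self-contained.

In the likelihood-based families, background rows are weighted by
`n_presence / n_background` so both classes carry equal total weight —
common presence/background practice.

Each model's binarization threshold is fitted on *training* scores at the
point where sensitivity equals specificity (candidates are the observed
scores and their midpoints; ties go to the smallest threshold; scores equal
to the threshold count as present). For random forests the training scores
are the out-of-bag vote fractions; in-bag votes sit near 0/1 and would
misplace the threshold. Thresholds are then frozen for every projection, so
future maps never see test data. Evaluation reports test-split AUC
(Mann–Whitney with ties counted 1/2), TSS (= sensitivity + specificity − 1),
percent correctly classified, a Swets accuracy class (> 0.9 high, 0.7–0.9
good, < 0.7 low), calibration bins, and Bernoulli deviance residuals with
probabilities clamped at 1e-6.

The five binary maps are summed into an agreement ensemble (0–5) and the
present consensus map keeps cells where at least `k_models = 3` (60%)
families agree.

**3. Futures and change.** Each future scenario (RCP × horizon) is realized
by four pseudo-GCMs. Within a GCM, the five models predict on the shifted
climate stack, are binarized at the frozen thresholds, and combined at
`k_models`; the four per-GCM consensus maps are then summed and cells with
at least `k_gcms = 2` agreeing GCMs form the future map. GCM consensus
deliberately follows model consensus — the protocol's "at least three
models and two GCMs" ordering. (Pooling all 20 binaries first is a
reasonable alternative; it is not the default because it lets one
over-permissive GCM compensate for another.) Comparing present and future
maps classifies each cell by its bit pair: (1,1) stable, (0,1) gain, (1,0)
loss, (0,0) unsuitable. Areas are summed with latitude-aware pixel areas,
`(cellsize · 111.195 km)² · cos(lat)` per row — the spherical
cosine-of-latitude rule with Earth circumference 40,030.2 km — and every
percentage is expressed relative to the *present* suitable area
(stable + loss), which is why gains can exceed 100%. Horizon averages
report both percentages recomputed from mean areas and means of the
one-decimal printed percentages, because published tables use the latter.
Report tables round half-up to one decimal; raw doubles are retained in
every returned object.

## Terrain predictors

- **TRI** (terrain ruggedness index): mean absolute elevation difference
  between a cell and its 8 neighbors in a 3×3 window; border cells are
  nodata.
- **Slope / aspect**: Horn 8-neighbor finite differences, slope in percent
  rise, aspect in degrees clockwise from north of the downslope direction,
  flat cells nodata. Degree cell sizes are converted to meters at each
  row's latitude. For modeling, aspect defaults to its northness/eastness
  (cosine/sine) encoding because raw degrees are circular; raw degrees
  remain available.
- **Distance layers**: exact Euclidean distance transforms
  (Felzenszwalb–Huttenlocher two-pass) on a local equirectangular
  projection with the east–west meter scale evaluated at the grid's mean
  latitude — adequate for study regions a few degrees across. Escape
  terrain is every cell with slope ≥ 30° (≈ 57.7% rise), with no minimum
  patch size; riparian distance uses the riparian mask the same way.

## Raster conventions

Grids are geographic (lon/lat), north-up, cell-center registered;
point-in-cell membership uses half-open intervals `[west, east)` ×
`(south, north]`. Nodata is `NA` internally and a sentinel (−9999) only on
disk; any operation touching nodata yields nodata. I/O uses the ESRI ASCII
Grid format — plain text, readable by GDAL/ArcGIS — written with 17
significant digits so round trips are exact. Alignment resamples onto a
template grid: continuous layers bilinearly, categorical by nearest
neighbor; aligning an aligned stack is a no-op.

## The synthetic landscape and virtual species

Every downstream stage is testable without external data because the
generator produces a landscape with known truth. Its defaults are the
package's reference study conditions:

- **Grid**: 300 × 300 cells of 30 arc-sec (~2.5° on a side) in a
  high-mountain latitude band (37–39.5° N).
- **DEM**: a correlated Gaussian random field (FFT-smoothed white noise,
  correlation length 40 cells) plus a north–south gradient (north higher)
  and a fine-scale relief component (amplitude 1 s.d., correlation 1.2
  cells), linearly rescaled to 3,300–7,300 m. The fine component matters:
  without it a ~900 m-cell DEM has no slopes ≥ 30° and the escape-terrain
  predictor would be undefined. About 1–3% of cells qualify as escape
  terrain, and median slopes sit near 25% — a rugged but mostly traversable
  landscape.
- **Climate**: annual mean temperature follows a −6.5 °C/km lapse rate on
  the DEM plus correlated noise (s.d. 0.5 °C); the driest-quarter
  temperature tracks it 3 °C lower; diurnal range, isothermality,
  temperature seasonality, and precipitation seasonality are independent
  structured fields; warmest-quarter precipitation increases
  orographically with elevation. The deliberate collinearity (bio9 ~ bio1)
  exercises the pruning stage the way real WorldClim layers would.
- **Riparian network**: a smoothed independent field thresholded at 7% of
  cells — a sinuous valley-network stand-in, since real riparian mapping
  has no single defining algorithm.
- **Virtual species**: suitability is the product of a plateau-shaped
  (generalized Gaussian, exponent 4) temperature response — optimum −8 °C
  (≈ 4,300 m under the lapse model), width 2 °C — and two bounded
  modifiers: an increasing logistic in TRI (midpoint 150 m, scale 60 m,
  floored at 0.5) and an exponential decay with riparian distance
  (e-folding 25 km, floored at 0.6). The surface is min–max rescaled so
  the best cell scores 1 (the usual virtual-species convention), making
  "suitability ≥ 0.5" a meaningful half-max core. The floors keep
  temperature the dominant planted driver; the plateau gives the species a
  contiguous core of realistic areal extent and steep niche shoulders, so
  the generated data support discrimination in the AUC ≈ 0.83–0.93 range
  that published mountain-ungulate ENMs report. Occurrences are sampled
  with probability proportional to suitability, with replacement (so
  clustered multi-point cells occur, as in field sighting data) and
  uniform jitter within the cell.
- **Scenarios**: pseudo-GCM deltas add a spatially uniform warming offset
  (+1.5/+2.0 °C for the moderate pathway at 2050/2070; +2.5/+4.0 °C for
  the extreme pathway) and scale precipitation down (×0.95/0.93 and
  ×0.90/0.85), magnitudes in line with mid- and end-century projections
  for continental mountain regions and a drying trend. The four GCMs
  share the pathway forcing and differ by seeded correlated noise
  (s.d. 0.3 °C; 4% on precipitation), emulating inter-model disagreement.
  Warming is ordered by construction: extreme ≥ moderate, and later ≥
  earlier within a pathway.

**What passing tests do and do not show.** The generator produces smooth,
stationary random fields with a known low-dimensional truth. It does not
emulate survey bias (detectability, access), non-stationary
climate-topography relationships, land-cover dynamics, dispersal limits, or
biotic interactions. Recovery results on this landscape therefore
demonstrate that the pipeline's statistics are implemented correctly and
that its protocol can recover a recoverable signal — not that any real
species' forecast is accurate. One further caveat: the discrimination
ceiling of a realization varies with the landscape draw; roughly 1 in 15
seeds yields a geometry where even the true suitability scores below
AUC 0.80 against MCP background, so single-seed accuracy numbers should be
read with that sampling variability in mind.

## Numerical choices and degenerate inputs

- AUC uses midranks, so ties contribute 1/2 exactly; both score sets must
  be nonempty.
- The sens=spec threshold search is a finite sweep over observed scores and
  midpoints; on continuous scores the residual |sens − spec| gap is at most
  `1/min(n1, n0)`.
- Constant predictors have undefined correlations; pruning treats them as
  `|r| = 0` and warns.
- Degenerate (collinear) presence hulls, empty masks for distance
  transforms, single-class training tables, non-finite predictor values,
  zero-suitability sampling surfaces, and zero present-day suitable area
  all fail loudly rather than producing silent output.
- Rejection sampling for background points caps its iterations and reports
  failure rather than looping forever on a degenerate hull/mask pair.
- All stochastic steps (field generation, splits, background, per-family
  seeds, GCM noise, permutation importance) derive from one master seed;
  xgboost runs single-threaded so boosted-tree fits are bit-reproducible.

## Problem sizes

The default study conditions (300 × 300 cells, 976 raw occurrences, 10,000
background points, five families, 4 GCMs × 2 RCPs × 2 horizons) run end to
end in a few minutes on one CPU; the test suite exercises the same code on
compact landscapes (40–150 cells on a side, 2–3 fast-configured families)
chosen so each property is tested at the smallest scale at which it is
meaningful, with the full default-scale protocol exercised by the
acceptance checks.

## Known limitations

- Geographic (lon/lat) grids only; areas use the spherical
  cosine-of-latitude rule rather than an ellipsoidal or projected
  calculation (differences are well under the rounding used in reports).
- The distance transform's single east–west scale is a small approximation
  for grids spanning many degrees of latitude.
- MARS is additive (no interaction terms), matching its typical ecological
  use but not the full MARS algorithm space.
- The Maxent equivalence omits threshold/product features and Maxent's
  specific regularization schedule; it is a penalized-logistic analogue,
  not a numerical replica of the Java implementation.
- Future projections hold terrain, land cover, and the riparian network
  fixed; only climate layers shift.
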