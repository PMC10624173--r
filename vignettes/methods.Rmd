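---
title: "Methods: AHP-weighted soil quality indexing for land-suitability assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP-weighted soil quality indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilsuit)
```

## The model

`soilsuit` implements a weighted linear soil quality index for evaluating
the suitability of agricultural land — here parameterised for wheat–barley
cultivation on semi-arid soils. The index for a location is

$$\mathrm{SQI} = \sum_{i=1}^{n} W_i \, X_i,$$

where $X_i \in [0.1, 1]$ is the standardized suitability score of soil
indicator $i$ and $W_i$ is its global weight, with $\sum_i W_i = 1$. The
index is mapped to a 0–100 scale (`index100 = 100 * SQI`) and classified
into the FAO-style suitability classes S1 (very good, 80–100), S2 (good,
60–80), S3 (medium, 50–60), N1 (weak, 20–50) and N2 (bad, 0–20).

The workflow has five stages, each usable on its own:

1. **Scoring** (`ssf_more_is_better()`, `ssf_less_is_better()`,
   `score_samples()`): piecewise-linear standard scoring functions map a
   raw indicator to $[0.1, 1]$ between a lower threshold $L$ and an upper
   threshold $U$.
2. **Weighting** (`derive_weights()`, `consistency()`,
   `global_weights()`): analytic-hierarchy-process pairwise comparisons
   yield weights per hierarchy level; a two-level hierarchy (main criteria
   over indicator groups) is flattened by multiplication.
3. **Interpolation** (`predict_surface()`, `loocv_rmse()`,
   `select_best()`, `rasterize_surface()`): point surveys become
   continuous surfaces; fifteen candidate interpolators compete on
   leave-one-out cross-validated RMSE.
4. **Index mapping** (`compute_sqi()`, `compute_sqi_raster()`,
   `classify_sqi()`, `mask_and_map()`, `tabulate_areas()`).
5. **Validation** (`validate_yield()`): regression of observed yields on
   the index, summarised by $R^2$.

A seeded generator (`synthetic_survey()`) produces synthetic surveys with
the statistical structure this workflow assumes, so every stage is
testable without field data.

## Standard scoring functions

Both SSF branches are linear ramps with a floor of 0.1 rather than 0 (a
worthless level of one indicator should not annihilate the index):

* more is better: $0.1$ for $x \le L$; $0.1 + 0.9\,(x-L)/(U-L)$ between;
  $1$ for $x \ge U$;
* less is better: the mirror image, $1$ below $L$ and $0.1$ above $U$.

The two branches always sum to 1.1 and both equal 0.55 at the midpoint.
The built-in catalog (`default_threshold_catalog()`) fixes the direction
of all 24 indicators (positive: depth, AWC, HC, clay, CEC, OM, N, P, Ca,
Mg, K, Fe, Cu, Zn, Mn; negative: slope, BD, sand, silt, pH, EC, CaCO3,
Na, ESP) and derives $L$ and $U$ from published wheat requirement class
edges where those are numeric and monotone: $L$ is the worst-class edge
and $U$ the fully-suitable edge (e.g. slope 0–30 %, depth 20–120 cm, OM
0.5–2 %, pH 7.0–8.5). Two conventions in that table deserve note:

* the total-nitrogen row mixes units; we read its class edges as
  0.045–0.32 % (the only decimally coherent reading);
* texture fractions (clay, silt, sand), hydraulic conductivity, Cu and
  Fe have categorical, one-sided or non-monotone requirement rows, so
  their thresholds default to the survey's 5th/95th percentiles instead.
  Each catalog entry records which rule produced it (`rule` column), and
  a YAML round trip (`write_threshold_catalog()` /
  `load_threshold_catalog()`) is exact.

A single linear ramp cannot express an interior optimum (e.g. pH both too
low and too high); the catalog scores alkalinity, the relevant failure
mode on these calcareous soils. Categorical texture-class scoring is out
of scope.

## AHP weighting and consistency

Weights default to the principal right eigenvector of the pairwise
matrix, computed by deterministic power iteration (uniform start,
relative tolerance $10^{-10}$, at most 10,000 iterations). The
column-normalized row-mean approximation often quoted in applied texts is
available as `method = "column_normalized_row_mean"`; for a perfectly
consistent matrix the two coincide. The eigenvector method is the default
because it reproduces the published wheat–barley main-criteria weights
(0.4934 / 0.3108 / 0.1958) to four decimals.

Consistency is certified by $\lambda_{\max}$ (the mean of the
component-wise ratios $(A w)_i / w_i$, exactly the principal eigenvalue
when $w$ is the eigenvector), $CI = (\lambda_{\max} - n)/(n-1)$, the
tabulated random index $RI(n)$, and $CR = CI/RI \le 0.10$. Orders 1–2 are
always consistent; their CR is defined as 0 because $RI$ vanishes there.

For the built-in wheat–barley hierarchy the four CRs compute to 0.0955
(physical, $8\times8$), 0.0918 (chemical, $6\times6$), 0.0903
(productivity, $10\times10$) and 0.0462 (main, $3\times3$) — all
acceptable. The published summary table for this hierarchy prints a
main-criteria CI/CR pair (0.032449 / 0.055946) that does not satisfy the
$CI$ definition against its own printed $\lambda_{\max}$ (3.053618, which
we reproduce); this package reports the internally consistent values and
does not chase those cells. Matrices typed by experts should be validated
in strict Saaty mode (`strict_saaty = TRUE`); matrices transcribed from
published tables often contain decimals such as 0.5 and load with the
check relaxed.

## Interpolation and model selection

Fifteen interpolators are enumerated in a fixed order (IDW powers 1–3;
thin-plate, completely regularized and tension splines; ordinary, simple
and universal kriging, each with gaussian, spherical and exponential
semivariogram models). Choices the underlying literature leaves open were
fixed as follows:

* **Cross-validation** is leave-one-out, the convention of geostatistical
  software RMSE tables. For kriging the variogram model is fitted once on
  the full sample and held fixed across folds (as geostatistical
  cross-validation routines conventionally do); the kriging system itself
  is re-solved for every fold.
* **Variograms**: method-of-moments estimator on 12 equal-width distance
  bins up to half the maximum pairwise distance, fitted by weighted least
  squares with pair-count weights and a nugget floored at 0 (L-BFGS-B,
  deterministic initialisation). Ranges are "practical" ranges (the
  exponential model reaches 95 % of its sill at the fitted range).
* **Simple kriging** uses the sample mean as its known mean; **universal
  kriging** a first-order (linear in x, y) drift.
* **RBF kernels**: thin-plate $r^2 \log r$ with a full linear polynomial;
  completely regularized and tension splines in their standard
  formulations (modified Bessel $K_0$), with the kernel scale defaulting
  to the mean nearest-neighbour distance.
* **IDW** is global (all points); distances are Euclidean on projected
  metre coordinates.
* All interpolators are **exact**: a query within $10^{-9}$ m of a sample
  returns the measured value, the convention of GIS interpolation suites
  (kriging with a fitted nugget would otherwise smooth over its data).
* Ties in `select_best()` break deterministically by enumeration order.
* Duplicate sample locations make the RBF/kriging systems singular and
  are reported with the offending pair.

Rasters are ESRI ASCII grids; `rasterize_surface()` can set cells beyond
a configurable buffer around the sample convex hull to no-data.

## Synthetic surveys

`synthetic_survey()` emulates the statistical signature of a semi-arid
~4,200 ha survey sampled at 400 m (its default 6.48 km square yields 256
points): each indicator is a stationary Gaussian random field with
exponential covariance, simulated by circulant embedding (negative
embedding eigenvalues, rare at this padding, are clamped and the clamped
mass recorded), then transformed cell-wise to the indicator's marginal
moments. Near-symmetric marginals ($|\text{skew}| < 0.05$) use an affine
map; all others a moment-matched shifted lognormal (reflected for
negative skew), whose shape parameter solves
$\gamma = (w + 2)\sqrt{w - 1}$, $w = e^{\sigma^2}$. The lognormal route is
used even for mild skewness so that indicators with published skewness
around 0.2–0.5 reproduce its sign and size. Values are clipped to the
marginal's observed range and the clipped fraction logged; for indicators
whose published moments imply strong truncation (slope: min 1, mean 5.1,
SD 6.9) this fraction is substantial by construction.

The correlation length defaults to 800 m — twice the sampling interval —
which makes interpolation meaningfully better than the field mean, as the
workflow assumes; no variography was published to estimate it from.
Fields are independent across indicators by default (real soil properties
covary, but no cross-correlations are asserted); yields are generated as
`base + gain * SQI + noise`, with defaults solved so yields span roughly
900–3,000 kg ha⁻¹ with mean ≈ 1,600 and a population $R^2$ on SQI of
0.67.

**What passing tests do and do not show.** The generator reproduces
marginal moments, spatial autocorrelation, the survey geometry and an
SQI–yield link of realistic strength. It does not emulate terrain,
geology, land-cover geometry, cross-correlated indicators or measurement
error, so passing its tests demonstrates the pipeline's internal
correctness and statistical behaviour, not agreement with any particular
real landscape.

## Numerical and test-design choices

* **Class boundaries.** The published class table (80–100, 79–60, 59–50,
  49–20, 19–0) leaves integer gaps; the package resolves them as
  half-open intervals $[l, u)$ with S1 closed at 100 — exhaustive,
  non-overlapping, order-preserving.
* **Index bridge.** Scores live in $[0.1, 1]$ while classes are on
  0–100; `index100 = 100 * SQI` is the only mapping that connects the
  two scales.
* **SQI orders.** Both pipeline orders are implemented:
  interpolate-then-score (default, matching the conventional flow in
  which parameter maps precede the index map) and score-then-interpolate;
  the run manifest records which ran.
* **Missing data** propagate as missing; a point or cell missing any
  weighted score has no index unless `renormalize = TRUE`, which rescales
  the remaining weights and records the fact.
* **Dense-sampling recovery.** The headline property test regenerates a
  survey whose true SQI raster is known and requires ≥ 90 % of cells to
  receive the true class. Exponential-covariance realizations are
  non-differentiable, so exact interpolation error decays only like
  $\sqrt{h/L}$ in the sampling interval $h$; the test therefore samples
  at $h = L/40$ (well inside the $h \le L/2$ regime, with every
  evaluation cell offset from every sample) on a 600 m domain with 10 m
  cells — about 900 points and 3,600 cells, which keeps the suite fast.
  At the study-like $h = L/2$ the same pipeline recovers ≈ 75 % of
  cells: a consequence of field roughness, not of the estimator.
* **Problem sizes.** Moment checks use the default 81×81 field (6,561
  cells ≥ 1,000) over 20 seeds with a 3-standard-error band based on the
  effective sample size $n_\mathrm{eff} = \text{area}/(2\pi L^2)$; the
  yield check uses 64 points over 50 seeds, matching the published
  validation survey's size.

## Known limitations

* No reprojection or geodesy: coordinates are planar metres throughout.
* Anisotropic variograms, co-kriging and fuzzy/group AHP are out of
  scope.
* GeoTIFF export is not provided; rasters are ESRI ASCII text grids.
* The published RMSE leaderboards and map areas of the motivating survey
  depend on its raw point data and undisclosed GIS settings; this package
  reproduces the method, with its own cross-validated leaderboard per
  parameter.
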