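---
title: "From FPAR time series to regional abundance models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FPAR time series to regional abundance models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhitools)
```

## The problem

Broad-scale wildlife monitoring programs, such as Russia's winter track
counts, report animal abundance at the level of administrative regions over
decades. Explaining the spatial pattern of those abundances requires
region-level summaries of habitat quality. `dhitools` implements a complete
workflow for this problem with vegetation productivity at its core: the
Dynamic Habitat Indices (DHIs) condense a multi-year satellite FPAR record
into three per-pixel quantities, and multiple linear regression relates
log-transformed regional densities to the DHIs and to climatic and
human-influence covariates.

## The Dynamic Habitat Indices

FPAR (fraction of absorbed photosynthetically active radiation) is a 0--1
productivity proxy observed every few days. For a composite seasonal year
$f_1, \dots, f_P$ (the cross-year median per period), the three indices
per pixel are

* **cumulative DHI** $= \sum_t f_t$ — total annual productivity,
* **minimum DHI** $= \min_t f_t$ — the annual productivity low,
* **variation DHI** $= \operatorname{sd}(f)/\operatorname{mean}(f)$ —
  seasonality, as a coefficient of variation.

`composite_fpar()` pools the median over years and, for 8-day inputs, over
pairs of consecutive periods into 16-day composites (the conventional
cadence for composite DHIs); `target_period_days` exposes this choice.
Numerical decisions worth knowing:

* The standard deviation in variation DHI uses the sample ($n-1$)
  denominator by default; `sd_denom = "population"` switches to $n$.
  A single available period leaves the CV undefined (`NA`).
* Winter darkness at high latitude leaves FPAR unobserved. Cumulative DHI
  sums the available periods without rescaling; minimum DHI sets pixels
  with any composite gap to zero (`darkness_fill`), treating the gap as
  the annual low — gaps in these data occur only in winter. Variation DHI
  uses the gap-omitted series. Rescaling the cumulative sum and a
  zero-filled variation series are plausible alternatives; the defaults
  keep each band's rule independent and explicit.
* A pixel unobserved everywhere is `NA` in all three bands.

## Habitat and density

Annual land-cover maps disagree between years, so habitat is defined on
*stable* land cover (`stable_landcover()`): a cell keeps a class only if
that class was observed there in strictly more than half of the years.
Ties at exactly half fail the rule — a deliberately conservative, literal
reading — and nodata years count toward the denominator. Suitable habitat
(`habitat_mask()`) is the intersection of stable membership in the suitable
class set (forests, open shrublands, woody savannas, permanent wetlands:
IGBP codes 1, 2, 3, 4, 5, 7, 8, 11 by default) with the species range
mask, consumed as a raster; rasterizing a vector range is the caller's
job.

Regional density divides yearly counts by the region's suitable habitat
area and averages over the analysis period (`region_density()`), then takes
the natural log. Missing survey values are repaired first
(`interpolate_missing()`): interior gaps linearly between the nearest
observed years, edge gaps by nearest-value extension (`zoo::na.approx`,
`rule = 2`) — the interior rule is standard, the edge rule is our choice
since a survey series offers nothing to extrapolate a trend from. Regions
with zero habitat or zero density are excluded from log-space modelling
with a warning rather than offset-adjusted. The among-region CV of density
per year (`cv_across_regions()`), summarized by decade medians, serves as
a survey data-quality diagnostic.

## Model selection

All models are ordinary least squares on region rows. The selection
workflow (`run_pipeline()` stages `screen` → `subsets` → `refine`)
mirrors standard ecological practice:

1. **Collinearity screen** — the full Pearson matrix plus average-linkage
   hierarchical clustering on $1 - \rho^2$ (squared Spearman correlation);
   within clusters above the similarity threshold only one nominated
   representative survives. The threshold defaults to $\rho^2 = 0.5$: a
   round value at which half of one variable's rank variation is shared
   with another, and deliberately configurable because no principled
   universal cutoff exists.
2. **Best subsets** — exhaustive enumeration of all predictor subsets up
   to `max_size`, ranked by BIC computed as
   $n\ln(\mathrm{RSS}/n) + k\ln n$ with $k$ counting the intercept.
   Because the additive constant of BIC is convention-dependent, only BIC
   *differences* are meaningful across software. An (essentially) exact
   fit is flagged `-Inf` and ties are broken by model size, then by label,
   so rankings are deterministic and never hinge on floating-point noise
   in a zero RSS.
3. **VIF refinement** — $\mathrm{VIF}_j = 1/(1 - R^2_j)$; predictors are
   dropped greedily (largest first) while any VIF is at or above 10, the
   conventional harmful-collinearity threshold.

RMSE is reported with denominator $n$ (a predictive-accuracy summary, not
an unbiased $\sigma$ estimate); `rmse_denom = "df"` is available.
Residual spatial structure is checked with an empirical semivariogram
(`residual_semivariogram()`), by default on great-circle distances between
region centroids; a flat semivariogram supports treating regions as
exchangeable observations.

## Decade comparisons

`decade_comparison()` refits one specification to each decade
(1981--1990, 1991--2000, 2001--2010) and tests pairwise equality of the
regression by the extra-sum-of-squares F test: the reduced model pools the
two decades, the full model frees intercept and slopes,
$F = \frac{(\mathrm{RSS_{red}} - \mathrm{RSS_{full}})/\Delta k}
{\mathrm{RSS_{full}}/(n - k_{full})}$.
The joint test (intercept and slopes together) is the default because a
single p-value per decade pair implies a joint contrast; `test = "slopes"`
isolates the slopes by giving the reduced model decade-specific
intercepts. Both are exposed since either reading is defensible.

## The synthetic scenario generator

`generate_scenario()` produces every pipeline input from a known
generative model, so each stage can be validated against ground truth:

* **FPAR**: a per-pixel sinusoid $m + a\cos 2\pi(\tau - \tau_{peak})$ with
  region-level mean and amplitude following the latitude gradient (lower
  mean, stronger seasonality northwards), pixel-level jitter, i.i.d.
  noise, clipped to $[0,1]$. The northern `darkness_latitude_fraction` of
  rows loses its winter periods, emulating polar-night gaps.
* **Land cover**: latitude bands (shrubland north, boreal forest belt,
  mixed/deciduous belt, cropland south with wetland patches) with 15%
  i.i.d. annual misclassification flips — enough churn to exercise the
  stability rule without destroying the map. Each region's seed cell is
  held at mixed forest in every year, guaranteeing at least 1 km² of
  habitat per region so density is defined in every Monte-Carlo draw.
* **Regions**: a jittered regular lattice of seeds and nearest-seed
  (Voronoi) assignment gives contiguous regions of varying size.
* **Covariates**: BIO1/BIO4/BIO7/BIO12 follow fixed, physically sensible
  recipes (temperature falls northwards, continentality rises east);
  remaining BIOCLIM variables, elevation and human footprint combine
  random gradient weights with smooth low-frequency random fields.
  Synthetic temperatures are in plain °C (real WorldClim files use
  °C × 10; documented where files are read).
* **Truth**: the configured covariates are summarized over habitat per
  region *by the same zonal code the pipeline uses*, z-scored across
  regions, and combined with `beta` plus $N(0, \sigma)$ into a true log
  density. Defaults are `beta = (2.0, 0.5, -0.3)` on (cumulative DHI,
  BIO1) and `sigma = 0.25`, chosen to match the residual scale (RMSE
  ≈ 0.25 on log density) a well-fitting regional abundance model
  exhibits.
* **Counts**: yearly expected counts are density × habitat area × a
  national trajectory multiplier (rise to a peak at year 11, a 42%
  collapse to year 22, partial recovery; normalized to mean 1 so long-run
  averages recover the truth), with Poisson noise — a natural
  mean–variance link for integer counts; the survey's true error
  structure is unknown, so this is a stand-in, not an inference. About
  0.3% of cells are removed at random and one survey year is missing
  entirely, mirroring the gaps interpolation must repair.
  `count_model = "expected"` disables count noise for noiseless
  validation scenarios.

What the generator does *not* emulate: sensor compositing artifacts,
spatially correlated survey error, region-boundary changes, observer
effort trends, or real road networks (road length is tabulated per
region). Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under a plausible data-generating process — not
that the fitted ecological relationships transfer to any particular real
dataset.

## Validation strategy and problem sizes

The test suite checks each operation against independent oracles
(nested-loop DHI recomputation, normal-equations fits, exhaustive subset
enumeration, base-R `anova` for the F test, `car::vif`) and the pipeline
end to end: noiseless scenarios must be refit exactly ($R^2_{adj} = 1$,
true support selected by BIC); with `sigma = 0.1`, 200 scenario draws at
the default 30 × 50 grid with 62 regions must cover every true
coefficient within ±3 SE in at least 95% of draws; and the extra-SS test
must hold its nominal 5% size within binomial 99% bounds over 500
simulated decade pairs. These sizes keep the full suite to a few minutes
on one core while leaving Monte-Carlo error well below the margins being
asserted.

## Known limitations

* Rasters are plain in-memory matrices with ESRI ASCII grid I/O; there is
  no projection handling, so inputs must share a grid (an equal-area grid
  is assumed when counting cells into km²). `resample_majority()` covers
  the one common mismatch, a finer categorical grid.
* OLS with exhaustive enumeration is exponential in the candidate count;
  intended for the tens of candidates typical here, not hundreds.
* The BIC constant and RMSE denominator follow the documented
  conventions; absolute values from other software may differ by a
  constant even though rankings agree.
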