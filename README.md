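# dhitools

Dynamic Habitat Indices and regional wildlife abundance models in R.

Regional game surveys — such as winter track counts, which report moose
abundance per administrative region over decades — pose a recurring
question: how much of the spatial pattern in density can remotely sensed
vegetation productivity and environmental covariates explain? `dhitools`
implements the full workflow for answering it, from raw satellite FPAR
time series to decade-wise regression comparisons, together with a
synthetic-data generator with known ground truth so every stage is
testable without gigabytes of external rasters.

It is aimed at spatial ecologists and remote-sensing analysts who want the
pieces of this pipeline as plain, composable R functions operating on
matrices and data frames.

## What it computes

**Dynamic Habitat Indices.** From a multi-year stack of periodic FPAR
(0–1) values, `composite_fpar()` builds a median seasonal year
f₁, …, f_P per pixel and `compute_dhi()` derives

* cumulative DHI = Σₜ fₜ (annual productivity),
* minimum DHI = minₜ fₜ (annual low; winter-darkness gaps fill to 0),
* variation DHI = sd(f) / mean(f) (seasonality).

**Habitat.** `stable_landcover()` keeps a cell's class only if observed in
strictly more than half of the years; `habitat_mask()` intersects the
suitable classes (forests, shrublands, woody savannas, wetlands) with the
species range; `habitat_area_by_region()` tallies km² per region.

**Density.** `interpolate_missing()` repairs survey gaps (linear interior,
nearest-value edges), `region_density()` averages count / habitat-area
over a period and log-transforms, `cv_across_regions()` tracks survey
quality.

**Models.** `best_subsets()` enumerates every predictor subset and ranks
by BIC = n ln(RSS/n) + k ln n; `screen_collinearity()` clusters
candidates on 1 − ρ²(Spearman); `vif()` / `vif_refine()` enforce
VIF < 10; `residual_semivariogram()` checks residual spatial structure;
`extra_ss_test()` / `decade_comparison()` test equality of decade-specific
fits by the extra-sum-of-squares F test.

**Synthetic scenarios.** `generate_scenario()` draws all of the above's
inputs from a configurable generative model whose regional log densities
follow a known linear model (`beta`, `sigma`), including a national
rise–collapse–recovery trajectory, Poisson count noise, missing survey
cells and polar-night FPAR gaps.

## Worked example

```r
library(dhitools)

sc  <- generate_scenario(scenario_config(seed = 1, sigma = 0.1))
tab <- build_region_table(sc)   # DHIs -> habitat -> density -> zonal means
bs  <- best_subsets(tab, "log_density",
                    c("dhi_cum", "dhi_var", "bio1", "bio4",
                      "elevation", "road_density"), max_size = 3)
print(bs, n = 4)
#> <subset_search> response: log_density -- 42 models
#>   rank                      model size    bic delta_bic     r2 r2_adj    rmse
#> 1    1             dhi_cum + bio1    2 -283.3     0.000 0.8638 0.8592 0.09216
#> 2    2 dhi_cum + bio1 + elevation    3 -282.0     1.312 0.8698 0.8631 0.09009
#> 3    3   dhi_cum + dhi_var + bio1    3 -279.5     3.734 0.8647 0.8577 0.09187
#> 4    4      dhi_cum + bio1 + bio4    3 -279.2     4.071 0.8639 0.8569 0.09212
```

The BIC-best model is exactly the pair that generated the data, and the
refit recovers the generating coefficients within sampling error:

```r
recover_coefficients(sc)$comparison
#>          term true estimate     se
#> 1 (Intercept)  2.0    2.010 0.0120
#> 2     dhi_cum  0.5    0.446 0.0333
#> 3        bio1 -0.3   -0.247 0.0333
```

Here `rank 1` means lowest BIC; `delta_bic` is the gap to it (models
within ~2 are statistically interchangeable), `r2_adj` the
predictor-penalized variance explained, and `rmse` the fit error on log
density. The full nine-stage pipeline — simulate, DHIs, habitat, density,
covariates, collinearity screen, best subsets, VIF refinement, decade
comparison — runs with one call and writes plain-text artifacts plus a
checksum manifest:

```r
run_pipeline(pipeline_config(seed = 1), "run1")
```

A thin command-line wrapper lives at `inst/cli/dhipipe.R`
(`Rscript dhipipe.R run-all --seed 1 --out run1`).

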