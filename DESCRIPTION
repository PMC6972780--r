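Package: dhitools
Title: Dynamic Habitat Indices and Regional Wildlife Abundance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Dynamic Habitat Indices (cumulative, minimum and
    variation of FPAR) from multi-year stacks of periodic
    vegetation-productivity rasters, derives stable land-cover maps and
    suitable-habitat masks, converts per-region winter track counts into
    interpolated log densities, summarizes raster covariates by region over
    suitable habitat, and fits and selects multiple linear regression models
    for regional abundance (exhaustive best-subsets search ranked by BIC,
    collinearity screening via Pearson correlations and squared-Spearman
    clustering, variance inflation factors, residual semivariograms, and
    extra-sum-of-squares comparisons of decade-specific fits). Includes a
    synthetic-scenario generator with known ground truth so the whole
    pipeline can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    zoo,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
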