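test_that("configuration invariants are enforced", {
  expect_error(scenario_config(sigma = -0.1), "sigma")
  expect_error(scenario_config(grid_height = 4, grid_width = 4,
                               n_regions = 62), "capacity")
  expect_error(scenario_config(suitable_classes = c(1, 99)), "subset")
  expect_error(scenario_config(beta = c(1, 2)), "covariate_names")
  expect_error(scenario_config(missing_abundance_fraction = 1), "\\[0, 1\\)")
  expect_error(scenario_config(n_years_fpar = 0), "count")
})

test_that("the same configuration yields a bit-identical bundle", {
  cfg <- tiny_scenario_config(seed = 77)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1, s2)
  s3 <- generate_scenario(tiny_scenario_config(seed = 78))
  expect_false(identical(s1$abundance$count, s3$abundance$count))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_scenario(tiny_scenario_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("generated rasters and tables satisfy the structural invariants", {
  sc <- generate_scenario(tiny_scenario_config(seed = 13))
  v <- sc$fpar$values
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  # region map partitions the grid
  expect_false(anyNA(sc$region_map))
  expect_setequal(unique(as.vector(sc$region_map)), 1:8)
  # winter darkness gaps only in the northern rows
  na_rows <- which(apply(is.na(v), 1, any))
  expect_true(all(na_rows <= round(0.3 * 12)))
  # abundance covers every (region, year) cell
  expect_equal(nrow(sc$abundance), 8 * 10)
  expect_false(anyDuplicated(sc$abundance[c("region_id", "year")]) > 0)
  # trajectory multiplier has mean one
  expect_equal(mean(sc$truth$trajectory$multiplier), 1)
  # centroids fall inside the map extent
  expect_true(all(sc$truth$region_centroids$lon >= min(sc$lon) &
                    sc$truth$region_centroids$lon <= max(sc$lon)))
})

test_that("a noiseless scenario is refit perfectly by the pipeline", {
  cfg <- tiny_scenario_config(seed = 21, sigma = 0, count_model = "expected",
                              missing_abundance_fraction = 0,
                              missing_years = integer(0))
  sc <- generate_scenario(cfg)
  rc <- recover_coefficients(sc)
  expect_equal(rc$fit$r2_adj, 1, tolerance = 1e-9)
  expect_equal(rc$comparison$estimate, rc$comparison$true, tolerance = 1e-7)
})

test_that("higher residual noise lowers the median refit R2_adj", {
  med_r2 <- vapply(c(0.05, 0.4, 1.2), function(sg) {
    r2 <- vapply(1:6, function(s) {
      sc <- generate_scenario(tiny_scenario_config(seed = 300 + s, sigma = sg))
      recover_coefficients(sc)$fit$r2_adj
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})

test_that("degrade_abundance removes the exact count, deterministically", {
  ab <- flat_abundance(62, years = 1981:2010)
  expect_identical(degrade_abundance(ab, 0), ab)
  d <- degrade_abundance(ab, 0.003, seed = 9)
  expect_equal(sum(is.na(d$count)), 6L)  # round(0.003 * 1860)
  d2 <- degrade_abundance(ab, 0.003, seed = 9)
  expect_identical(d, d2)
  # heavy degradation never exhausts a region's series
  d5 <- degrade_abundance(ab, 0.5, seed = 10)
  kept <- tapply(!is.na(d5$count), d5$region_id, sum)
  expect_true(all(kept >= 2))
  expect_equal(sum(is.na(d5$count)), round(0.5 * nrow(ab)))
  expect_error(degrade_abundance(ab, 1), "\\[0, 1\\)")
})

test_that("scenario round-trips to disk as plain-text artifacts", {
  dir <- withr::local_tempdir()
  sc <- generate_scenario(tiny_scenario_config(seed = 31))
  write_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "region_map.asc")))
  rm2 <- read_ascii_grid(file.path(dir, "region_map.asc"))
  expect_equal(unname(rm2[, ]), unname(sc$region_map[, ]),
               ignore_attr = TRUE)
  ab <- read.csv(file.path(dir, "abundance.csv"))
  expect_equal(nrow(ab), nrow(sc$abundance))
  cfg2 <- read_scenario_config(file.path(dir, "scenario.yaml"))
  expect_equal(unclass(cfg2), unclass(sc$config))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta, sc$truth$beta)
})
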