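#' Configuration for a synthetic study scenario
#'
#' Defines the generative model for a complete set of pipeline inputs:
#' a multi-year periodic FPAR stack with a seasonal cycle and winter
#' darkness gaps in the north, annual land-cover rasters, a Voronoi tiling
#' of administrative regions, bioclimatic / elevation / human-influence
#' covariate rasters, and a 30-year regional abundance table whose log
#' density follows a known linear model of region-level covariates.
#'
#' The defaults mirror the study conditions the package is built around:
#' 62 regions, 12 years of 46 eight-day FPAR periods, 10 land-cover years,
#' 30 abundance years starting 1981 with a national rise-collapse-recovery
#' trajectory, about 0.3% randomly missing abundance cells plus one fully
#' missing survey year (1996).
#'
#' @param grid_height,grid_width Grid size in cells (1 km2 cells on a
#'   notional equal-area grid).
#' @param n_regions Number of administrative regions.
#' @param n_years_fpar Years in the FPAR stack.
#' @param periods_per_year FPAR periods per year.
#' @param period_length_days Days per FPAR period.
#' @param first_fpar_year First FPAR year label.
#' @param n_years_landcover Years of annual land cover.
#' @param n_years_abundance Years of abundance surveys.
#' @param first_abundance_year First survey year.
#' @param landcover_classes Integer class codes in play.
#' @param suitable_classes Subset of codes counted as habitat.
#' @param covariate_names Region-level covariates entering the true
#'   log-density model (columns of the assembled design table; each is
#'   z-scored across regions before the coefficients apply).
#' @param beta True coefficients: intercept followed by one slope per
#'   covariate in `covariate_names`.
#' @param sigma Residual standard deviation of log density (>= 0).
#' @param missing_abundance_fraction Fraction of (region, year) cells set
#'   missing at random, in `[0, 1)`.
#' @param missing_years Survey years missing for every region (the
#'   default emulates the fully missing 1996 survey).
#' @param darkness_latitude_fraction Fraction of northern rows whose winter
#'   FPAR periods are unobserved.
#' @param count_model `"poisson"` (integer counts, mean = density x habitat
#'   area; the default) or `"expected"` (exact noiseless expected counts,
#'   for noiseless validation scenarios).
#' @param lon_range,lat_range Geographic extent in degrees (row 1 is the
#'   northern edge).
#' @param cell_area_km2 Cell area.
#' @param seed Integer RNG seed; the whole bundle is a deterministic
#'   function of the configuration.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(grid_height = 30, grid_width = 50,
                            n_regions = 62,
                            n_years_fpar = 12, periods_per_year = 46,
                            period_length_days = 8,
                            first_fpar_year = 2003,
                            n_years_landcover = 10,
                            n_years_abundance = 30,
                            first_abundance_year = 1981,
                            landcover_classes = 0:16,
                            suitable_classes = suitable_classes_default(),
                            covariate_names = c("dhi_cum", "bio1"),
                            beta = c(2.0, 0.5, -0.3),
                            sigma = 0.25,
                            missing_abundance_fraction = 0.003,
                            missing_years = 1996,
                            darkness_latitude_fraction = 0.3,
                            count_model = c("poisson", "expected"),
                            lon_range = c(30, 140), lat_range = c(50, 70),
                            cell_area_km2 = 1,
                            seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(grid_height = grid_height, grid_width = grid_width,
              n_regions = n_regions,
              n_years_fpar = n_years_fpar,
              periods_per_year = periods_per_year,
              period_length_days = period_length_days,
              first_fpar_year = first_fpar_year,
              n_years_landcover = n_years_landcover,
              n_years_abundance = n_years_abundance,
              first_abundance_year = first_abundance_year,
              landcover_classes = as.integer(landcover_classes),
              suitable_classes = as.integer(suitable_classes),
              covariate_names = covariate_names,
              beta = beta, sigma = sigma,
              missing_abundance_fraction = missing_abundance_fraction,
              missing_years = as.integer(missing_years),
              darkness_latitude_fraction = darkness_latitude_fraction,
              count_model = count_model,
              lon_range = lon_range, lat_range = lat_range,
              cell_area_km2 = cell_area_km2,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  counts <- c("grid_height", "grid_width", "n_regions", "n_years_fpar",
              "periods_per_year", "n_years_landcover", "n_years_abundance")
  for (nm in counts) {
    if (!is_count(cfg[[nm]])) stop(nm, " must be a count >= 1", call. = FALSE)
  }
  if (cfg$n_regions > cfg$grid_height * cfg$grid_width) {
    stop("n_regions exceeds grid capacity (", cfg$grid_height, " x ",
         cfg$grid_width, " cells)", call. = FALSE)
  }
  if (!all(cfg$suitable_classes %in% cfg$landcover_classes)) {
    stop("suitable_classes must be a subset of landcover_classes",
         call. = FALSE)
  }
  if (!(is.numeric(cfg$sigma) && cfg$sigma >= 0)) {
    stop("sigma must be >= 0", call. = FALSE)
  }
  if (length(cfg$beta) != length(cfg$covariate_names) + 1L) {
    stop("length(beta) must equal length(covariate_names) + 1", call. = FALSE)
  }
  f <- cfg$missing_abundance_fraction
  if (!(is.numeric(f) && f >= 0 && f < 1)) {
    stop("missing_abundance_fraction must lie in [0, 1)", call. = FALSE)
  }
  d <- cfg$darkness_latitude_fraction
  if (!(is.numeric(d) && d >= 0 && d <= 1)) {
    stop("darkness_latitude_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$grid_height, "x", x$grid_width, " grid, ",
      x$n_regions, " regions, seed ", x$seed, "\n", sep = "")
  cat("  FPAR: ", x$n_years_fpar, " yr x ", x$periods_per_year, " periods (",
      x$period_length_days, "-day); abundance: ", x$n_years_abundance,
      " yr from ", x$first_abundance_year, "\n", sep = "")
  cat("  truth: log density ~ ", paste(x$covariate_names, collapse = " + "),
      ", beta = (", paste(format(x$beta), collapse = ", "),
      "), sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

# sum of a few random low-frequency sine waves, normalized to unit sd:
# a cheap spatially autocorrelated field
smooth_field <- function(H, W, n_waves = 4) {
  row_i <- matrix(seq_len(H), H, W)
  col_j <- matrix(seq_len(W), H, W, byrow = TRUE)
  f <- matrix(0, H, W)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 2.5) / W
    fy <- stats::runif(1, 0.5, 2.5) / H
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * sin(2 * pi * (fx * col_j + fy * row_i) + ph)
  }
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# jittered regular lattice of seeds -> nearest-seed (Voronoi) region tiling;
# every seed keeps its own cell so no region is empty
make_region_map <- function(H, W, k) {
  nr <- max(1L, round(sqrt(k * H / W)))
  nc <- ceiling(k / nr)
  while (nr * nc < k) nr <- nr + 1L
  centers_r <- as.vector(outer((seq_len(nr) - 0.5) * H / nr,
                               rep(1, nc)))[seq_len(k)]
  centers_c <- as.vector(outer(rep(1, nr),
                               (seq_len(nc) - 0.5) * W / nc))[seq_len(k)]
  centers_r <- pmin(pmax(centers_r + stats::runif(k, -0.35, 0.35) * H / nr,
                         0.51), H + 0.49)
  centers_c <- pmin(pmax(centers_c + stats::runif(k, -0.35, 0.35) * W / nc,
                         0.51), W + 0.49)
  seed_cell <- cbind(round(centers_r), round(centers_c))
  # deduplicate seed cells deterministically
  key <- (seed_cell[, 1] - 1) * W + seed_cell[, 2]
  for (i in seq_len(k)) {
    while (i > 1L && key[i] %in% key[seq_len(i - 1L)]) {
      key[i] <- (key[i] %% (H * W)) + 1
    }
  }
  seed_cell <- cbind((key - 1) %/% W + 1, (key - 1) %% W + 1)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  best_d <- matrix(Inf, H, W)
  map <- matrix(NA_integer_, H, W)
  for (i in seq_len(k)) {
    d <- (rows - centers_r[i])^2 + (cols - centers_c[i])^2
    upd <- d < best_d
    map[upd] <- i
    best_d[upd] <- d[upd]
  }
  map[seed_cell] <- seq_len(k)
  list(map = map, seed_cells = seed_cell)
}

#' Generate a complete synthetic scenario bundle
#'
#' Draws every pipeline input from the generative model in
#' [scenario_config()]. Region-level truth: the configured covariates are
#' summarized over suitable habitat per region exactly as the analysis
#' pipeline does, z-scored across regions, and combined with `beta` plus
#' `N(0, sigma)` noise into a true log density per region; yearly counts are
#' the true density times a national trajectory multiplier (mean 1 over the
#' study years, with a peak-to-trough decline of 42% around the 11th and
#' 22nd years) times habitat area, with Poisson noise under the default
#' count model. Identical configurations yield bit-identical bundles; the
#' caller's RNG state is left untouched.
#'
#' @param config A [scenario_config()].
#' @return A `dhi_scenario` list: `fpar` ([fpar_stack()]), `landcover`
#'   ([landcover_stack()]), `region_map`, `range_mask`, `covariates` (named
#'   list of rasters: `bio1`..`bio19`, `elevation`, `human_footprint`),
#'   `abundance` (region, year, count), `roads`, `region_area`,
#'   `rural_population`, `truth` (beta, sigma, covariate names, centroids,
#'   trajectory, true densities), `lon`, `lat`, `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  with_preserved_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cfg) {
  H <- cfg$grid_height; W <- cfg$grid_width; k <- cfg$n_regions
  npix <- H * W
  reg <- make_region_map(H, W, k)
  lon <- seq(cfg$lon_range[1], cfg$lon_range[2], length.out = W)
  lat <- seq(cfg$lat_range[2], cfg$lat_range[1], length.out = H)  # N -> S
  northness_row <- (lat - min(lat)) / max(diff(range(lat)), 1e-9)
  northness <- matrix(northness_row, H, W)
  eastness <- matrix((lon - min(lon)) / max(diff(range(lon)), 1e-9),
                     H, W, byrow = TRUE)

  # --- land cover: latitude bands + wetland patches + inter-annual flips ---
  base_lc <- matrix(NA_integer_, H, W)
  band <- findInterval(1 - northness, c(0, 0.25, 0.60, 0.85, 1), all.inside = TRUE)
  forest_draw <- matrix(sample(c(1L, 3L, 5L), npix, replace = TRUE), H, W)
  south_draw <- matrix(sample(c(4L, 5L), npix, replace = TRUE), H, W)
  base_lc[band == 1] <- 7L                      # northern open shrublands
  base_lc[band == 2] <- forest_draw[band == 2]  # boreal forest belt
  base_lc[band == 3] <- south_draw[band == 3]   # mixed/deciduous belt
  base_lc[band == 4] <- 12L                     # southern croplands
  wet <- matrix(stats::runif(npix) < 0.05, H, W) & band == 4
  base_lc[wet] <- 11L
  base_lc[] <- ifelse(base_lc %in% cfg$landcover_classes, base_lc,
                      cfg$landcover_classes[1])
  lc <- array(NA_integer_, c(H, W, cfg$n_years_landcover))
  for (y in seq_len(cfg$n_years_landcover)) {
    flip <- matrix(stats::runif(npix) < 0.15, H, W)
    alt <- matrix(sample(cfg$landcover_classes, npix, replace = TRUE), H, W)
    yr <- base_lc
    yr[flip] <- alt[flip]
    lc[, , y] <- yr
  }
  # guarantee habitat in every region: the seed cell is mixed forest (or the
  # first suitable class) in every year
  anchor <- if (5L %in% cfg$suitable_classes) 5L else cfg$suitable_classes[1]
  for (y in seq_len(cfg$n_years_landcover)) {
    sl <- lc[, , y]
    sl[reg$seed_cells] <- anchor
    lc[, , y] <- sl
  }
  landcover <- landcover_stack(lc)

  # --- FPAR: regional sinusoid parameters, pixel jitter, iid noise ---
  region_north <- as.numeric(tapply(northness[!is.na(reg$map)],
                                    reg$map[!is.na(reg$map)], mean))
  m_r <- pmin(pmax(0.55 - 0.35 * region_north + stats::rnorm(k, 0, 0.03),
                   0.05), 0.95)
  a_r <- pmin(pmax(0.15 + 0.20 * region_north + stats::rnorm(k, 0, 0.03),
                   0.02), 0.45)
  m_px <- matrix(m_r[reg$map], H, W) + stats::rnorm(npix, 0, 0.02)
  a_px <- matrix(a_r[reg$map], H, W) + stats::rnorm(npix, 0, 0.02)
  a_px <- pmax(a_px, 0.01)
  P <- cfg$periods_per_year; Y <- cfg$n_years_fpar
  tau <- (seq_len(P) - 0.5) / P
  peak <- 0.54  # fraction of year at the productivity peak (mid-July)
  season <- cos(2 * pi * (tau - peak))
  arr <- array(stats::rnorm(npix * P * Y, 0, 0.02), c(H, W, P, Y))
  arr <- arr + as.vector(m_px) +
    rep(as.vector(a_px), times = P * Y) *
      rep(rep(season, each = npix), times = Y)
  arr <- pmin(pmax(arr, 0), 1)
  dim(arr) <- c(H, W, P, Y)
  if (cfg$darkness_latitude_fraction > 0) {
    n_dark <- round(cfg$darkness_latitude_fraction * H)
    if (n_dark > 0) {
      wc <- (peak + 0.5) %% 1
      circ <- pmin(abs(tau - wc), 1 - abs(tau - wc))
      winter <- which(circ < 0.125)
      arr[seq_len(n_dark), , winter, ] <- NA_real_
    }
  }
  fpar <- fpar_stack(arr, period_length_days = cfg$period_length_days,
                     year_labels = cfg$first_fpar_year +
                       seq_len(Y) - 1L)

  range_mask <- matrix(TRUE, H, W)

  # --- covariate rasters -------------------------------------------------
  covr <- list()
  covr$bio1 <- 15 - 25 * northness + 2 * smooth_field(H, W) +
    matrix(stats::rnorm(npix, 0, 0.5), H, W)
  covr$bio4 <- 600 + 500 * northness + 300 * eastness +
    80 * smooth_field(H, W)
  covr$bio7 <- 25 + 20 * northness + 10 * eastness + 2 * smooth_field(H, W)
  covr$bio12 <- pmax(700 - 400 * eastness + 120 * smooth_field(H, W) +
                       matrix(stats::rnorm(npix, 0, 20), H, W), 50)
  for (j in setdiff(1:19, c(1, 4, 7, 12))) {
    w1 <- stats::runif(1, -1, 1); w2 <- stats::runif(1, -1, 1)
    scale_j <- if (j <= 11) 8 else 150  # temperature- vs precipitation-like
    covr[[paste0("bio", j)]] <-
      scale_j * (w1 * northness + w2 * eastness + 0.6 * smooth_field(H, W))
  }
  covr <- covr[paste0("bio", 1:19)]
  covr$elevation <- pmax(200 + 900 * pmax(eastness - 0.5, 0) * northness +
                           250 * smooth_field(H, W), 0)
  covr$human_footprint <- pmax(5 + 30 * (1 - northness) +
                                 4 * smooth_field(H, W), 0)

  # --- habitat, region covariate means, truth ---------------------------
  stable <- stable_landcover(landcover)
  hmask <- habitat_mask(stable, cfg$suitable_classes, range_mask,
                        cell_area_km2 = cfg$cell_area_km2)
  areas <- habitat_area_by_region(hmask, reg$map)
  stopifnot(all(areas$habitat_km2 > 0))
  dhi <- compute_dhi(fpar)
  zonal <- c(list(dhi_cum = dhi$cumulative, dhi_min = dhi$minimum,
                  dhi_var = dhi$variation), covr)
  ztabs <- lapply(names(zonal), function(nm)
    zonal_mean(zonal[[nm]], reg$map, hmask, name = nm))
  names(ztabs) <- names(zonal)
  region_area <- data.frame(
    region_id = seq_len(k),
    area_km2 = as.numeric(table(factor(reg$map, levels = seq_len(k)))) *
      cfg$cell_area_km2)
  roads <- data.frame(
    region_id = seq_len(k),
    road_km = region_area$area_km2 *
      pmax(0.05 + 0.4 * (1 - region_north) +
             stats::rnorm(k, 0, 0.05), 0.01))
  design0 <- assemble_design(c(ztabs, list(
    road_density = road_density(roads, region_area))))
  miss_cov <- setdiff(cfg$covariate_names, names(design0))
  if (length(miss_cov)) {
    stop("covariate_names not generated: ", paste(miss_cov, collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(as.matrix(design0[cfg$covariate_names]))
  eta <- cfg$beta[1] + as.numeric(Z %*% cfg$beta[-1])
  log_density <- eta + stats::rnorm(k, 0, cfg$sigma)
  density_true <- exp(log_density)

  # --- yearly counts along the national trajectory ----------------------
  years <- cfg$first_abundance_year + seq_len(cfg$n_years_abundance) - 1L
  traj <- national_trajectory(cfg$n_years_abundance)
  lambda <- outer(density_true * areas$habitat_km2, traj)  # region x year
  counts <- if (cfg$count_model == "poisson") {
    matrix(stats::rpois(length(lambda), lambda), nrow = k)
  } else {
    lambda
  }
  abundance <- data.frame(
    region_id = rep(seq_len(k), times = length(years)),
    year = rep(years, each = k),
    count = as.numeric(counts))
  if (length(cfg$missing_years)) {
    abundance$count[abundance$year %in% cfg$missing_years] <- NA_real_
  }
  if (cfg$missing_abundance_fraction > 0) {
    abundance <- degrade_abundance(abundance, cfg$missing_abundance_fraction,
                                   seed = cfg$seed + 1L)
  }

  rural <- do.call(rbind, lapply(c("1991-2000", "2001-2010"), function(lbl)
    data.frame(region_id = seq_len(k), period = lbl,
               rural_population = round(pmax(
                 region_area$area_km2 * (5 + 40 * (1 - region_north)) *
                   exp(stats::rnorm(k, 0, 0.2)), 10)))))

  centroids <- region_centroids(reg$map, lon, lat)
  truth <- list(beta = cfg$beta, sigma = cfg$sigma,
                covariate_names = cfg$covariate_names,
                region_centroids = centroids,
                trajectory = data.frame(year = years, multiplier = traj),
                density = density_true, log_density = log_density)
  structure(list(fpar = fpar, landcover = landcover,
                 region_map = reg$map, range_mask = range_mask,
                 covariates = covr, abundance = abundance,
                 roads = roads, region_area = region_area,
                 rural_population = rural,
                 truth = truth, lon = lon, lat = lat, config = cfg),
            class = "dhi_scenario")
}

# national population multiplier over the survey years: rise to a peak at
# ~1/3 of the series, collapse by 42% to a trough at ~2/3, partial recovery;
# normalized to mean 1 so long-run average densities equal the truth
national_trajectory <- function(n_years) {
  if (n_years == 1L) return(1)
  anchors_x <- round(c(0, 10 / 29, 21 / 29, 1) * (n_years - 1)) + 1
  anchors_x <- pmin(pmax(anchors_x, 1), n_years)
  anchors_y <- c(0.75, 1.25, 0.725, 0.9)
  m <- stats::approx(anchors_x, anchors_y, xout = seq_len(n_years),
                     ties = "ordered")$y
  m / mean(m)
}

#' @export
print.dhi_scenario <- function(x, ...) {
  cfg <- x$config
  cat("<dhi_scenario> ", cfg$grid_height, "x", cfg$grid_width, " grid, ",
      cfg$n_regions, " regions, seed ", cfg$seed, "\n", sep = "")
  cat("  truth: log density ~ ",
      paste(cfg$covariate_names, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Flag a fraction of abundance cells as missing
#'
#' Marks exactly `round(fraction * n_cells)` entries missing, drawn
#' uniformly but never reducing any region below two observed years (so a
#' region's series can always be interpolated and no region loses its whole
#' series). Deterministic for a given seed; the caller's RNG state is
#' preserved.
#'
#' @param table Abundance table `(region_id, year, count)`.
#' @param fraction Fraction of cells to remove, in `[0, 1)`.
#' @param seed Integer seed for the removal draw.
#' @return The table with the selected counts set to `NA`.
#' @export
degrade_abundance <- function(table, fraction, seed = 1L) {
  check_abundance(table)
  if (!(is.numeric(fraction) && fraction >= 0 && fraction < 1)) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  n_remove <- round(fraction * nrow(table))
  if (n_remove == 0L) return(table)
  with_preserved_seed(seed, {
    ord <- sample.int(nrow(table))
    observed <- tapply(!is.na(table$count), table$region_id, sum)
    taken <- integer(0)
    for (i in ord) {
      if (length(taken) >= n_remove) break
      if (is.na(table$count[i])) next
      rid <- as.character(table$region_id[i])
      if (observed[[rid]] <= 2L) next
      observed[[rid]] <- observed[[rid]] - 1L
      taken <- c(taken, i)
    }
    if (length(taken) < n_remove) {
      stop("cannot remove ", n_remove,
           " cells without exhausting a region's series", call. = FALSE)
    }
    table$count[taken] <- NA_real_
    table
  })
}
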