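#' Build the per-region design table from a scenario bundle
#'
#' Runs the analysis stages that turn raw scenario inputs into the model
#' table: DHIs from the FPAR stack, stable land cover and the habitat mask,
#' habitat areas, interpolated counts and log density over `years`, zonal
#' covariate means over habitat, and road density -- then inner-joins
#' everything by region.
#'
#' @param scenario A `dhi_scenario` from [generate_scenario()].
#' @param years Survey years to average density over (default: all).
#' @param include_rural Append the scenario's decade rural-population column
#'   (only defined for the periods it covers).
#' @return Data frame with one row per region: `region_id`, `dhi_cum`,
#'   `dhi_min`, `dhi_var`, `bio1`..`bio19`, `elevation`, `human_footprint`,
#'   `road_density`, `density`, `log_density` (and `rural_population` when
#'   requested).
#' @export
build_region_table <- function(scenario, years = NULL,
                               include_rural = FALSE) {
  stopifnot(inherits(scenario, "dhi_scenario"))
  cfg <- scenario$config
  dhi <- compute_dhi(scenario$fpar)
  stable <- stable_landcover(scenario$landcover)
  hmask <- habitat_mask(stable, cfg$suitable_classes, scenario$range_mask,
                        cell_area_km2 = cfg$cell_area_km2)
  areas <- habitat_area_by_region(hmask, scenario$region_map)
  ab <- interpolate_missing(scenario$abundance)
  dens <- region_density(ab, areas, years = years)
  rasters <- c(list(dhi_cum = dhi$cumulative, dhi_min = dhi$minimum,
                    dhi_var = dhi$variation), scenario$covariates)
  ztabs <- lapply(names(rasters), function(nm)
    zonal_mean(rasters[[nm]], scenario$region_map, hmask, name = nm))
  names(ztabs) <- names(rasters)
  tabs <- c(ztabs, list(
    road_density = road_density(scenario$roads, scenario$region_area),
    density = dens[c("region_id", "density", "log_density")]))
  if (include_rural) {
    lbl <- dens$period[1]
    rp <- scenario$rural_population
    rp <- rp[rp$period == lbl, c("region_id", "rural_population")]
    if (nrow(rp)) tabs$rural <- rp
  }
  assemble_design(tabs)
}

#' Refit the generating model of a scenario and compare with truth
#'
#' Rebuilds the design table through the full pipeline, z-scores the true
#' covariates across regions (as the generative model does) and refits the
#' log-density regression by OLS.
#'
#' @param scenario A `dhi_scenario`.
#' @param table Optionally a prebuilt [build_region_table()] result.
#' @return List with `fit` (a `dhi_fit`) and `comparison`: data frame
#'   `(term, true, estimate, se)` for the intercept and each true slope.
#' @export
recover_coefficients <- function(scenario, table = NULL) {
  stopifnot(inherits(scenario, "dhi_scenario"))
  truth <- scenario$truth
  if (is.null(table)) table <- build_region_table(scenario)
  Z <- scale(as.matrix(table[truth$covariate_names]))
  zt <- data.frame(log_density = table$log_density, Z)
  names(zt)[-1] <- truth$covariate_names
  fit <- fit_ols(zt, model_spec("log_density", truth$covariate_names))
  comparison <- data.frame(
    term = c("(Intercept)", truth$covariate_names),
    true = truth$beta,
    estimate = as.numeric(fit$coefficients),
    se = as.numeric(fit$se))
  list(fit = fit, comparison = comparison)
}

#' Write a scenario bundle to disk as plain-text artifacts
#'
#' Rasters become ESRI ASCII grids, tables CSV, the configuration YAML and
#' the ground truth JSON.
#'
#' @param scenario A `dhi_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "dhi_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(scenario$region_map, file.path(dir, "region_map.asc"))
  write_ascii_grid(scenario$range_mask * 1, file.path(dir, "range_mask.asc"))
  for (nm in names(scenario$covariates)) {
    write_ascii_grid(scenario$covariates[[nm]],
                     file.path(dir, paste0(nm, ".asc")))
  }
  utils::write.csv(scenario$abundance, file.path(dir, "abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$roads, file.path(dir, "roads.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$region_area, file.path(dir, "region_area.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$rural_population,
                   file.path(dir, "rural_population.csv"), row.names = FALSE)
  write_scenario_config(scenario$config, file.path(dir, "scenario.yaml"))
  jsonlite::write_json(
    list(beta = scenario$truth$beta, sigma = scenario$truth$sigma,
         covariate_names = scenario$truth$covariate_names,
         region_centroids = scenario$truth$region_centroids),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a scenario configuration as YAML
#'
#' @param path YAML file mirroring the [scenario_config()] field names.
#' @return For `read_scenario_config`, a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @param config A `scenario_config`.
#' @return For `write_scenario_config`, `path` invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_stages <- function() {
  c("simulate", "dhi", "habitat", "density", "covariates",
    "screen", "subsets", "refine", "decades")
}

#' Configuration for the end-to-end pipeline
#'
#' @param scenario A [scenario_config()] describing the synthetic inputs
#'   (simulation is the first pipeline stage).
#' @param candidates Candidate predictors for model selection.
#' @param max_subset_size Largest model size enumerated by
#'   [best_subsets()].
#' @param vif_limit VIF threshold for [vif_refine()] (default 10).
#' @param cluster_threshold Squared-Spearman similarity threshold for
#'   [screen_collinearity()].
#' @param seed Pipeline seed (also overrides the scenario seed).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            candidates = c("dhi_cum", "dhi_min", "dhi_var",
                                           "bio1", "bio4", "bio7", "bio12",
                                           "elevation", "human_footprint",
                                           "road_density"),
                            max_subset_size = 4,
                            vif_limit = 10,
                            cluster_threshold = 0.5,
                            seed = 1L) {
  stopifnot(inherits(scenario, "scenario_config"),
            vif_limit > 0, cluster_threshold > 0)
  scenario$seed <- as.integer(seed)
  structure(list(scenario = scenario, candidates = candidates,
                 max_subset_size = max_subset_size, vif_limit = vif_limit,
                 cluster_threshold = cluster_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `scenario` key
#' holds [scenario_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$scenario)) {
    vals$scenario <- do.call(scenario_config, vals$scenario)
  }
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the nine stages -- simulate, dhi, habitat, density, covariates,
#' screen, subsets, refine, decades -- writing every artifact under
#' `out_dir` along with `manifest.json` (completed stages, md5 checksum of
#' every file, seed, configuration). Reruns with the same configuration and
#' seed reproduce all tables bit-identically. Any stage failure aborts with
#' the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Stages to run; because stages feed each other, everything
#'   up to the furthest requested stage is executed (default: all nine).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (the parsed manifest).
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[seq_len(max(match(stages, pipeline_stages())))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  res <- list()
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  log_file <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
    message(line)
  }
  logmsg("pipeline seed: ", config$seed)

  if ("simulate" %in% stages) {
    res$scenario <- run_stage("simulate", {
      sc <- generate_scenario(config$scenario)
      write_scenario(sc, file.path(out_dir, "inputs"))
      sc
    })
    done <- c(done, "simulate")
    logmsg("simulate: ", config$scenario$n_regions, " regions on ",
           config$scenario$grid_height, "x", config$scenario$grid_width)
  }
  sc <- res$scenario
  cfg <- sc$config

  if ("dhi" %in% stages) {
    res$dhi <- run_stage("dhi", {
      dhi <- compute_dhi(sc$fpar)
      write_dhi(dhi, file.path(out_dir, "dhi"))
      dhi
    })
    done <- c(done, "dhi")
    logmsg("dhi: ", attr(res$dhi, "n_periods"), " composite periods")
  }
  if ("habitat" %in% stages) {
    res$habitat <- run_stage("habitat", {
      stable <- stable_landcover(sc$landcover)
      hmask <- habitat_mask(stable, cfg$suitable_classes, sc$range_mask,
                            cell_area_km2 = cfg$cell_area_km2)
      areas <- habitat_area_by_region(hmask, sc$region_map)
      write_ascii_grid(stable, file.path(out_dir, "stable_landcover.asc"))
      write_ascii_grid(hmask * 1, file.path(out_dir, "habitat_mask.asc"))
      wcsv(areas, "habitat_area.csv")
      list(stable = stable, mask = hmask, areas = areas)
    })
    done <- c(done, "habitat")
    logmsg("habitat: ", sum(res$habitat$areas$habitat_km2), " km2 suitable")
  }
  if ("density" %in% stages) {
    res$density <- run_stage("density", {
      ab <- interpolate_missing(sc$abundance)
      dens <- region_density(ab, res$habitat$areas)
      yd <- yearly_density(ab, res$habitat$areas)
      cv_year <- cv_across_regions(yd, "year")
      wcsv(ab, "abundance_interpolated.csv")
      wcsv(dens, "density.csv")
      wcsv(cv_year, "cv_by_year.csv")
      wcsv(national_totals(ab), "national_totals.csv")
      list(abundance = ab, density = dens, cv_year = cv_year)
    })
    done <- c(done, "density")
    logmsg("density: ", nrow(res$density$density), " regions")
  }
  if ("covariates" %in% stages) {
    res$table <- run_stage("covariates", {
      tab <- build_region_table(sc)
      wcsv(tab, "covariates.csv")
      tab
    })
    done <- c(done, "covariates")
  }
  if ("screen" %in% stages) {
    res$screen <- run_stage("screen", {
      scr <- screen_collinearity(res$table, config$candidates,
                                 threshold = config$cluster_threshold)
      wcsv(data.frame(variable = names(scr$clusters),
                      cluster = as.integer(scr$clusters),
                      retained = names(scr$clusters) %in% scr$retained),
           "screen_clusters.csv")
      utils::write.csv(round(scr$pearson, 4),
                       file.path(out_dir, "pearson.csv"))
      scr
    })
    done <- c(done, "screen")
    logmsg("screen: retained ", length(res$screen$retained), " of ",
           length(config$candidates), " candidates")
  }
  if ("subsets" %in% stages) {
    res$subsets <- run_stage("subsets", {
      bs <- best_subsets(res$table, "log_density", res$screen$retained,
                         max_size = min(config$max_subset_size,
                                        length(res$screen$retained)))
      wcsv(as.data.frame(bs), "models.csv")
      bs
    })
    done <- c(done, "subsets")
    logmsg("subsets: best model '", res$subsets$model[1], "'")
  }
  if ("refine" %in% stages) {
    res$refine <- run_stage("refine", {
      start <- model_spec("log_density", top_model(res$subsets))
      ref <- withCallingHandlers(
        vif_refine(res$table, start, limit = config$vif_limit),
        message = function(m) {
          cat(conditionMessage(m), file = log_file, append = TRUE)
          invokeRestart("muffleMessage")
        })
      pr <- predict_residuals(ref$fit, res$table)
      cen <- region_centroids(sc$region_map, sc$lon, sc$lat)
      pr <- merge(cen, pr, by = "region_id")
      sv <- residual_semivariogram(pr$residual, pr[c("lon", "lat")],
                                   distance = "greatcircle")
      wcsv(data.frame(term = names(ref$fit$coefficients),
                      estimate = as.numeric(ref$fit$coefficients),
                      se = as.numeric(ref$fit$se)), "final_model.csv")
      if (!is.null(ref$vif)) {
        wcsv(data.frame(predictor = names(ref$vif),
                        vif = as.numeric(ref$vif)), "vif.csv")
      }
      wcsv(pr, "residuals.csv")
      wcsv(as.data.frame(sv), "semivariogram.csv")
      c(ref, list(residuals = pr, semivariogram = sv))
    })
    done <- c(done, "refine")
    logmsg("refine: final model '", format(res$refine$spec), "'",
           if (length(res$refine$dropped))
             paste0(" (dropped ",
                    paste(res$refine$dropped, collapse = ", "), ")") else "")
  }
  if ("decades" %in% stages) {
    res$decades <- run_stage("decades", {
      years_avail <- sort(unique(sc$abundance$year))
      dec <- Filter(function(y) all(y %in% years_avail), decade_years())
      if (length(dec) < 2L) stop("fewer than two complete decades of data")
      tables <- lapply(dec, function(y)
        build_region_table(sc, years = y,
                           include_rural = TRUE))
      shared <- Reduce(intersect, lapply(tables, names))
      cmp <- decade_comparison(lapply(tables, function(t) t[shared]),
                               res$refine$spec)
      fits_df <- do.call(rbind, lapply(names(cmp$fits), function(nm)
        data.frame(period = nm, model = format(cmp$fits[[nm]]$spec),
                   r2_adj = cmp$fits[[nm]]$r2_adj,
                   rmse = cmp$fits[[nm]]$rmse)))
      wcsv(fits_df, "decade_fits.csv")
      wcsv(cmp$tests, "decade_tests.csv")
      # rural population only exists for the post-1991 decades; report the
      # augmented fits without forcing the variable into the shared model
      rural_rows <- lapply(names(tables), function(nm) {
        t <- tables[[nm]]
        if (!"rural_population" %in% names(t)) return(NULL)
        aug <- model_spec(res$refine$spec$response,
                          c(res$refine$spec$predictors, "rural_population"))
        f <- fit_ols(t, aug)
        data.frame(period = nm, model = format(aug),
                   r2_adj = f$r2_adj, rmse = f$rmse)
      })
      rural_rows <- Filter(Negate(is.null), rural_rows)
      if (length(rural_rows)) {
        wcsv(do.call(rbind, rural_rows), "decade_rural_models.csv")
      }
      cmp
    })
    done <- c(done, "decades")
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  manifest <- list(
    stages = lapply(done, function(s) list(name = s, status = "completed")),
    seed = config$seed,
    files = as.list(sums),
    config = list(candidates = config$candidates,
                  max_subset_size = config$max_subset_size,
                  vif_limit = config$vif_limit,
                  cluster_threshold = config$cluster_threshold,
                  scenario = unclass(config$scenario)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("completed ", length(done), " stages")
  invisible(c(res, list(manifest = manifest)))
}
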