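#' Mean of a raster covariate over suitable habitat, by region
#'
#' @param raster Numeric matrix on the region grid.
#' @param regions Integer matrix of region ids (`NA` = background).
#' @param mask Optional logical matrix; when supplied, only cells where it
#'   is `TRUE` contribute (typically a [habitat_mask()]). Default: all cells.
#' @param name Column name for the mean in the output.
#' @return Data frame `(region_id, <name>)`; regions with no contributing
#'   cell get `NA` and are reported in a warning.
#' @export
zonal_mean <- function(raster, regions, mask = NULL, name = "mean") {
  stop_mismatch(raster, regions, "zonal_mean")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(raster), ncol(raster))
  stop_mismatch(raster, mask, "zonal_mean")
  ids <- sort(unique(regions[!is.na(regions)]))
  sel <- !is.na(regions) & mask & !is.na(raster)
  f <- factor(regions[sel], levels = ids)
  mu <- tapply(raster[sel], f, mean)
  mu <- as.numeric(mu)
  if (anyNA(mu)) {
    warning("no masked cells in region(s): ",
            paste(ids[is.na(mu)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(region_id = as.integer(ids), mean = mu)
  names(out)[2] <- name
  out
}

#' Road density per region
#'
#' Length of roads within a region divided by the region's total area.
#'
#' @param road_length_km Data frame `(region_id, road_km)`.
#' @param region_area_km2 Data frame `(region_id, area_km2)`; all areas > 0.
#' @return Data frame `(region_id, road_density)` in km per km2.
#' @export
road_density <- function(road_length_km, region_area_km2) {
  stopifnot(all(c("region_id", "road_km") %in% names(road_length_km)),
            all(c("region_id", "area_km2") %in% names(region_area_km2)))
  m <- merge(road_length_km, region_area_km2, by = "region_id")
  if (any(!(m$area_km2 > 0))) {
    stop("zero or negative region area for region(s): ",
         paste(m$region_id[!(m$area_km2 > 0)], collapse = ", "), call. = FALSE)
  }
  data.frame(region_id = m$region_id, road_density = m$road_km / m$area_km2)
}

#' Region centroids in map coordinates
#'
#' @param regions Integer matrix of region ids.
#' @param lon Numeric vector of column-centre longitudes (length `ncol`).
#' @param lat Numeric vector of row-centre latitudes (length `nrow`).
#' @return Data frame `(region_id, lon, lat)`: mean cell coordinates per
#'   region.
#' @export
region_centroids <- function(regions, lon, lat) {
  stopifnot(length(lon) == ncol(regions), length(lat) == nrow(regions))
  ids <- sort(unique(regions[!is.na(regions)]))
  lon_m <- matrix(lon, nrow(regions), ncol(regions), byrow = TRUE)
  lat_m <- matrix(lat, nrow(regions), ncol(regions))
  keep <- !is.na(regions)
  f <- factor(regions[keep], levels = ids)
  data.frame(region_id = as.integer(ids),
             lon = as.numeric(tapply(lon_m[keep], f, mean)),
             lat = as.numeric(tapply(lat_m[keep], f, mean)))
}

#' Assemble the per-region model design table
#'
#' Inner-joins any number of per-region tables on `region_id`, requiring the
#' same region set in every source: any region missing from any table aborts
#' the join with a message naming the table and the regions.
#'
#' @param ... Named data frames, each with a `region_id` column.
#' @return One data frame with one row per region and all columns.
#' @export
assemble_design <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.null(names(tabs)) && is.list(tabs[[1]]) &&
      !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  stopifnot(length(tabs) >= 1L)
  if (is.null(names(tabs)) || any(names(tabs) == "")) {
    names(tabs) <- paste0("table", seq_along(tabs))
  }
  for (nm in names(tabs)) {
    if (!"region_id" %in% names(tabs[[nm]])) {
      stop("table '", nm, "' lacks a region_id column", call. = FALSE)
    }
  }
  all_ids <- sort(unique(unlist(lapply(tabs, function(t) t$region_id))))
  for (nm in names(tabs)) {
    miss <- setdiff(all_ids, tabs[[nm]]$region_id)
    if (length(miss)) {
      stop("table '", nm, "' is missing region(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  out <- Reduce(function(a, b) merge(a, b, by = "region_id"), tabs)
  out <- out[order(out$region_id), , drop = FALSE]
  if (anyNA(out)) {
    bad <- names(out)[vapply(out, anyNA, logical(1))]
    stop("assembled design has missing values in: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
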