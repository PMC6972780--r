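#' Fill missing yearly counts by linear interpolation
#'
#' Interior gaps in each region's yearly count series are filled by linear
#' interpolation between the nearest observed years; gaps at the series
#' edges take the nearest observed value. Every region must have at least
#' two observed years.
#'
#' @param table Data frame `(region_id, year, count)`; `(region_id, year)`
#'   unique, counts >= 0 or `NA`.
#' @return The table with no missing counts, ordered by region then year.
#' @export
interpolate_missing <- function(table) {
  check_abundance(table)
  out <- table[order(table$region_id, table$year), , drop = FALSE]
  for (rid in unique(out$region_id)) {
    idx <- which(out$region_id == rid)
    cnt <- out$count[idx]
    if (sum(!is.na(cnt)) < 2L) {
      stop("region ", rid, " has fewer than 2 observed years; cannot interpolate",
           call. = FALSE)
    }
    if (anyNA(cnt)) {
      out$count[idx] <- zoo::na.approx(cnt, x = out$year[idx],
                                       na.rm = FALSE, rule = 2)
    }
  }
  rownames(out) <- NULL
  out
}

check_abundance <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("region_id", "year", "count") %in% names(table)))
  if (anyDuplicated(table[c("region_id", "year")])) {
    stop("(region_id, year) pairs must be unique", call. = FALSE)
  }
  if (any(table$count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' The three study decades
#'
#' @return Named list of year vectors: 1981-1990, 1991-2000, 2001-2010.
#' @export
decade_years <- function() {
  list("1981-1990" = 1981:1990,
       "1991-2000" = 1991:2000,
       "2001-2010" = 2001:2010)
}

period_label <- function(years) paste0(min(years), "-", max(years))

#' Average density per region over a set of years
#'
#' Density for a region-year is the count divided by the region's suitable
#' habitat area; the period density is the mean of the yearly densities over
#' the period, and `log_density` its natural log. Regions with zero or
#' missing habitat area, or zero period density, are dropped with a warning
#' (log density is undefined there).
#'
#' @param table Complete abundance table (see [interpolate_missing()]).
#' @param areas Data frame `(region_id, habitat_km2)`.
#' @param years Years to average over; default all years in `table`.
#' @return Data frame `(region_id, period, density, log_density)`,
#'   density in individuals per km2.
#' @export
region_density <- function(table, areas, years = NULL) {
  check_abundance(table)
  stopifnot(all(c("region_id", "habitat_km2") %in% names(areas)))
  if (is.null(years)) years <- sort(unique(table$year))
  if (length(years) == 0L) stop("empty year period", call. = FALSE)
  sub <- table[table$year %in% years, , drop = FALSE]
  if (anyNA(sub$count)) {
    stop("abundance table has missing counts; run interpolate_missing() first",
         call. = FALSE)
  }
  m <- merge(sub, areas, by = "region_id")
  absent <- setdiff(unique(sub$region_id), areas$region_id)
  bad <- unique(c(absent, areas$region_id[!(areas$habitat_km2 > 0)]))
  if (length(bad)) {
    warning("excluding region(s) with zero or missing habitat area: ",
            paste(sort(bad), collapse = ", "), call. = FALSE)
    m <- m[!(m$region_id %in% bad), , drop = FALSE]
  }
  dens <- tapply(m$count / m$habitat_km2, m$region_id, mean)
  out <- data.frame(region_id = as.integer(names(dens)),
                    period = period_label(years),
                    density = as.numeric(dens))
  zero <- out$region_id[!(out$density > 0)]
  if (length(zero)) {
    warning("excluding region(s) with zero period density: ",
            paste(zero, collapse = ", "), call. = FALSE)
    out <- out[out$density > 0, , drop = FALSE]
  }
  out$log_density <- log(out$density)
  rownames(out) <- NULL
  out
}

#' Yearly density per region
#'
#' @inheritParams region_density
#' @return Data frame `(region_id, year, density)`.
#' @export
yearly_density <- function(table, areas) {
  check_abundance(table)
  m <- merge(table, areas, by = "region_id")
  m <- m[m$habitat_km2 > 0, , drop = FALSE]
  out <- data.frame(region_id = m$region_id, year = m$year,
                    density = m$count / m$habitat_km2)
  out[order(out$region_id, out$year), , drop = FALSE]
}

#' Coefficient of variation of density across regions
#'
#' A data-quality diagnostic: the among-region CV (sample standard deviation
#' over mean) of density, per year; with `grouping = "decade"` the yearly
#' CVs are summarized by their median within each study decade.
#'
#' @param density_yearly Data frame `(region_id, year, density)` from
#'   [yearly_density()].
#' @param grouping `"year"` (default) or `"decade"`.
#' @return For `"year"`, a data frame `(year, cv, n_regions)`; for
#'   `"decade"`, `(decade, median_cv, n_years)`.
#' @export
cv_across_regions <- function(density_yearly, grouping = c("year", "decade")) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("region_id", "year", "density") %in% names(density_yearly)))
  years <- sort(unique(density_yearly$year))
  cvs <- vapply(years, function(y) {
    d <- density_yearly$density[density_yearly$year == y]
    d <- d[!is.na(d)]
    if (length(d) < 2L) stop("need at least 2 regions in year ", y, call. = FALSE)
    mu <- mean(d)
    if (mu == 0) stop("zero mean density in year ", y, call. = FALSE)
    stats::sd(d) / mu
  }, numeric(1))
  per_year <- data.frame(
    year = years, cv = cvs,
    n_regions = vapply(years, function(y)
      sum(density_yearly$year == y & !is.na(density_yearly$density)), integer(1)))
  if (grouping == "year") return(per_year)
  dec <- decade_years()
  rows <- lapply(names(dec), function(lbl) {
    sel <- per_year$year %in% dec[[lbl]]
    if (!any(sel)) return(NULL)
    data.frame(decade = lbl, median_cv = stats::median(per_year$cv[sel]),
               n_years = sum(sel))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Percent decline from a population peak to a trough
#'
#' @param peak,trough Population totals (same units).
#' @return Decline as a percentage of the peak, `100 * (peak - trough) / peak`.
#' @export
percent_decline <- function(peak, trough) {
  stopifnot(peak > 0)
  100 * (peak - trough) / peak
}

#' National yearly totals from a regional abundance table
#'
#' @inheritParams interpolate_missing
#' @return Data frame `(year, total)`, summing counts over regions
#'   (missing counts omitted).
#' @export
national_totals <- function(table) {
  check_abundance(table)
  tot <- tapply(table$count, table$year, sum, na.rm = TRUE)
  data.frame(year = as.integer(names(tot)), total = as.numeric(tot))
}
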