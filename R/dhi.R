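#' Construct a multi-year periodic FPAR stack
#'
#' FPAR (fraction of absorbed photosynthetically active radiation) is a 0-1
#' vegetation-productivity proxy observed on a regular sub-annual cadence
#' (e.g. 46 eight-day periods per year). The stack holds one layer per
#' (year, period) on a common grid; gaps (winter darkness, snow) are `NA`.
#'
#' @param values 4-d numeric array `[row, col, period, year]` with finite
#'   values in `[0, 1]` or `NA`.
#' @param period_length_days Length of one period in days.
#' @param year_labels Optional labels for the year dimension.
#' @return An object of class `fpar_stack`.
#' @export
fpar_stack <- function(values, period_length_days = 8, year_labels = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("FPAR values must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("FPAR values must be finite or NA", call. = FALSE)
  if (is.null(year_labels)) year_labels <- seq_len(dim(values)[4])
  stopifnot(length(year_labels) == dim(values)[4])
  structure(list(values = values,
                 period_length_days = period_length_days,
                 year_labels = year_labels),
            class = "fpar_stack")
}

#' @export
print.fpar_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<fpar_stack> ", d[1], "x", d[2], " grid, ", d[3], " periods (",
      x$period_length_days, "-day) x ", d[4], " years\n", sep = "")
  invisible(x)
}

#' Median-composite an FPAR stack into a single synthetic year
#'
#' Collapses the year dimension (and, when `target_period_days` is a multiple
#' of the stack's native period, groups of consecutive within-year periods)
#' by the median of all available values, yielding one typical seasonal
#' trajectory per pixel. A cell-period with no observation in any year stays
#' `NA`.
#'
#' @param stack An [fpar_stack()].
#' @param target_period_days Output period length in days; must be a multiple
#'   of `stack$period_length_days` that divides the year evenly. The default
#'   pools pairs of 8-day periods into 16-day composites (and leaves other
#'   cadences unaggregated).
#' @return A `composite_series`: list with `values` (`[row, col, period]`
#'   array) and `period_length_days`.
#' @export
composite_fpar <- function(stack, target_period_days = NULL) {
  stopifnot(inherits(stack, "fpar_stack"))
  d <- dim(stack$values)
  if (any(d == 0L)) stop("empty FPAR stack", call. = FALSE)
  p0 <- stack$period_length_days
  if (is.null(target_period_days)) {
    target_period_days <- if (p0 == 8) 16 else p0
  }
  if (target_period_days %% p0 != 0) {
    stop("target_period_days (", target_period_days,
         ") is not a multiple of the stack period (", p0, " days)",
         call. = FALSE)
  }
  k <- target_period_days %/% p0
  if (d[3] %% k != 0) {
    stop("cannot group ", d[3], " periods into blocks of ", k, call. = FALSE)
  }
  g <- d[3] %/% k
  out <- array(NA_real_, dim = c(d[1], d[2], g))
  npix <- d[1] * d[2]
  for (gi in seq_len(g)) {
    idx <- ((gi - 1L) * k + 1L):(gi * k)
    sub <- stack$values[, , idx, , drop = FALSE]
    m <- matrix(sub, nrow = npix)
    out[, , gi] <- matrix(row_medians(m), nrow = d[1])
  }
  structure(list(values = out, period_length_days = target_period_days),
            class = "composite_series")
}

series_matrix <- function(series) {
  stopifnot(inherits(series, "composite_series"))
  d <- dim(series$values)
  matrix(series$values, nrow = d[1] * d[2])
}

#' Cumulative DHI: per-pixel sum of the composite FPAR year
#'
#' Annual cumulative productivity -- the sum of the composite FPAR values
#' over the year. Missing periods are omitted from the sum (no rescaling;
#' see the methods vignette); a pixel missing in every period is `NA`.
#'
#' @param series A `composite_series` from [composite_fpar()].
#' @return Numeric matrix `[row, col]` of unitless summed FPAR.
#' @export
cumulative_dhi <- function(series) {
  m <- series_matrix(series)
  if (ncol(m) == 0L) stop("empty composite series", call. = FALSE)
  s <- rowSums(m, na.rm = TRUE)
  s[rowSums(!is.na(m)) == 0L] <- NA_real_
  matrix(s, nrow = dim(series$values)[1])
}

#' Minimum DHI: per-pixel annual low of the composite FPAR year
#'
#' Minimum productivity -- the lowest composite FPAR value during the year.
#' At high latitudes FPAR is unobserved in winter darkness; with
#' `darkness_fill = TRUE` (the default) a pixel whose composite year has one
#' or more missing periods is assigned 0, treating the gap as the annual
#' productivity low. A pixel missing in all periods stays `NA`.
#'
#' @inheritParams cumulative_dhi
#' @param darkness_fill Set pixels with winter observation gaps to zero.
#' @return Numeric matrix `[row, col]` in `[0, 1]`.
#' @export
minimum_dhi <- function(series, darkness_fill = TRUE) {
  m <- series_matrix(series)
  if (ncol(m) == 0L) stop("empty composite series", call. = FALSE)
  nobs <- rowSums(!is.na(m))
  mn <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
  mn[nobs == 0L] <- NA_real_
  if (isTRUE(darkness_fill)) {
    gap <- nobs > 0L & nobs < ncol(m)
    mn[gap] <- 0
  }
  matrix(mn, nrow = dim(series$values)[1])
}

#' Variation DHI: per-pixel coefficient of variation of the composite year
#'
#' Seasonality -- the standard deviation of the composite FPAR values over
#' the year divided by their mean, computed over available periods. Pixels
#' with non-positive mean (or a single available period, where the sample
#' standard deviation is undefined) are `NA`.
#'
#' @inheritParams cumulative_dhi
#' @param sd_denom Standard-deviation denominator: `"sample"` (n - 1, the
#'   default) or `"population"` (n).
#' @return Numeric matrix `[row, col]`, values >= 0.
#' @export
variation_dhi <- function(series, sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  m <- series_matrix(series)
  if (ncol(m) == 0L) stop("empty composite series", call. = FALSE)
  nobs <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  dev2 <- (m - mu)^2
  ss <- rowSums(dev2, na.rm = TRUE)
  denom <- if (sd_denom == "sample") pmax(nobs - 1L, 0L) else nobs
  sdv <- sqrt(ss / denom)
  cv <- sdv / mu
  cv[nobs == 0L | !(mu > 0) | (sd_denom == "sample" & nobs < 2L)] <- NA_real_
  matrix(cv, nrow = dim(series$values)[1])
}

#' Compute the three Dynamic Habitat Indices from an FPAR stack
#'
#' Composites the stack into a median year ([composite_fpar()]) and derives
#' cumulative, minimum and variation DHI per pixel. A pixel with no
#' observation anywhere is `NA` in all three bands.
#'
#' @inheritParams composite_fpar
#' @inheritParams minimum_dhi
#' @inheritParams variation_dhi
#' @return A `dhi_raster`: list of matrices `cumulative`, `minimum`,
#'   `variation`, with attribute `n_periods` (composite periods per year).
#' @export
compute_dhi <- function(stack, target_period_days = NULL,
                        darkness_fill = TRUE,
                        sd_denom = c("sample", "population")) {
  series <- composite_fpar(stack, target_period_days)
  out <- structure(
    list(cumulative = cumulative_dhi(series),
         minimum = minimum_dhi(series, darkness_fill = darkness_fill),
         variation = variation_dhi(series, sd_denom = sd_denom)),
    class = "dhi_raster")
  attr(out, "n_periods") <- dim(series$values)[3]
  out
}

#' @export
print.dhi_raster <- function(x, ...) {
  cat("<dhi_raster> ", nrow(x$cumulative), "x", ncol(x$cumulative),
      " grid, ", attr(x, "n_periods"), " composite periods\n", sep = "")
  for (b in c("cumulative", "minimum", "variation")) {
    r <- range(x[[b]], na.rm = TRUE)
    cat(sprintf("  %-10s [%.3f, %.3f]\n", b, r[1], r[2]))
  }
  invisible(x)
}

#' Write a DHI raster as three ASCII grids
#'
#' One file per band, named `<prefix>_cum.asc`, `<prefix>_min.asc`,
#' `<prefix>_var.asc`.
#'
#' @param dhi A `dhi_raster` from [compute_dhi()].
#' @param prefix Path prefix for the three output files.
#' @param ... Passed to [write_ascii_grid()].
#' @return Character vector of the three paths, invisibly.
#' @export
write_dhi <- function(dhi, prefix, ...) {
  stopifnot(inherits(dhi, "dhi_raster"))
  paths <- c(cumulative = paste0(prefix, "_cum.asc"),
             minimum = paste0(prefix, "_min.asc"),
             variation = paste0(prefix, "_var.asc"))
  for (b in names(paths)) write_ascii_grid(dhi[[b]], paths[[b]], ...)
  invisible(unname(paths))
}
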