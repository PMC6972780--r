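#' Empirical semivariogram of model residuals
#'
#' For every pair of regions, half the squared residual difference is
#' accumulated into distance bins: `gamma(h) = mean (z_i - z_j)^2 / 2` over
#' pairs whose separation falls in bin `h`. Used to check fitted models for
#' residual spatial autocorrelation (a flat semivariogram indicates none).
#'
#' @param residuals Numeric vector of residuals, one per location.
#' @param coords Data frame or matrix with two columns: `lon`, `lat` (or
#'   x, y for Euclidean distances), one row per residual.
#' @param n_bins Number of equal-width distance bins.
#' @param max_dist Upper bound of the last bin; default the maximum pair
#'   distance, so all `n(n-1)/2` pairs are binned.
#' @param distance `"euclidean"` on the raw coordinates, or
#'   `"greatcircle"` (haversine on lon/lat, distances in km).
#' @return A `semivariogram` data frame
#'   `(lag_mid, semivariance, n_pairs)`; empty bins have `NA`
#'   semivariance.
#' @export
residual_semivariogram <- function(residuals, coords, n_bins = 10,
                                   max_dist = NULL,
                                   distance = c("euclidean", "greatcircle")) {
  distance <- match.arg(distance)
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n, ncol(coords) == 2L)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (distance == "euclidean") {
    d <- as.matrix(stats::dist(coords))
  } else {
    d <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  }
  ut <- upper.tri(d)
  dist_ij <- d[ut]
  if (max(dist_ij) == 0) stop("all points are coincident", call. = FALSE)
  gamma_ij <- (outer(residuals, residuals, "-")^2 / 2)[ut]
  if (is.null(max_dist)) max_dist <- max(dist_ij)
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(dist_ij, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  keep <- !is.na(bin)
  sv <- tapply(gamma_ij[keep], factor(bin[keep], levels = seq_len(n_bins)),
               mean)
  cnt <- tapply(rep(1, sum(keep)), factor(bin[keep], levels = seq_len(n_bins)),
                sum)
  cnt[is.na(cnt)] <- 0
  out <- data.frame(
    lag_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    semivariance = as.numeric(sv),
    n_pairs = as.integer(cnt))
  structure(out, class = c("semivariogram", "data.frame"),
            distance = distance)
}
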