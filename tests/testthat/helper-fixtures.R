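# small fixtures shared across test files

tiny_scenario_config <- function(seed = 1L, ...) {
  scenario_config(grid_height = 12, grid_width = 18, n_regions = 8,
                  n_years_fpar = 3, periods_per_year = 8,
                  n_years_abundance = 10, seed = seed, ...)
}

# an FPAR stack with a known deterministic sinusoidal pixel trajectory,
# identical across years
sinusoid_stack <- function(H = 2, W = 2, P = 8, Y = 3, m = 0.5, a = 0.3,
                           peak = 0.54) {
  tau <- (seq_len(P) - 0.5) / P
  vals <- m + a * cos(2 * pi * (tau - peak))
  arr <- array(rep(rep(vals, each = H * W), times = Y), c(H, W, P, Y))
  fpar_stack(arr, period_length_days = 8)
}

# complete abundance table: one count column, no gaps
flat_abundance <- function(n_regions = 4, years = 2001:2010, count = 100) {
  ab <- expand.grid(region_id = seq_len(n_regions), year = years)
  ab$count <- count
  ab[order(ab$region_id, ab$year), ]
}

# region-level design matrix with independent standard-normal columns
random_design <- function(n = 62, vars, seed = 1) {
  set.seed(seed)
  out <- data.frame(region_id = seq_len(n))
  for (v in vars) out[[v]] <- rnorm(n)
  out
}

# independent nested-loop recomputation of the three DHIs (the oracle used
# against compute_dhi); no aggregation across within-year periods
dhi_loop_oracle <- function(values, darkness_fill = TRUE) {
  H <- dim(values)[1]; W <- dim(values)[2]; P <- dim(values)[3]
  cum <- mn <- cv <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      comp <- numeric(P)
      for (p in seq_len(P)) {
        v <- values[i, j, p, ]
        v <- v[!is.na(v)]
        comp[p] <- if (length(v)) median(v) else NA_real_
      }
      avail <- comp[!is.na(comp)]
      if (length(avail) == 0) next
      cum[i, j] <- sum(avail)
      mn[i, j] <- if (darkness_fill && anyNA(comp)) 0 else min(avail)
      if (mean(avail) > 0 && length(avail) >= 2) {
        cv[i, j] <- sd(avail) / mean(avail)
      }
    }
  }
  list(cumulative = cum, minimum = mn, variation = cv)
}

# independent exhaustive best-subsets enumeration via normal equations
subsets_enum_oracle <- function(table, response, candidates, max_size) {
  y <- table[[response]]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (s in 0:max_size) {
    combos <- if (s == 0) list(integer(0)) else
      asplit(combn(length(candidates), s), 2)
    for (idx in combos) {
      X <- cbind(1, as.matrix(table[candidates[idx]]))
      b <- solve(crossprod(X), crossprod(X, y))
      rss <- sum((y - X %*% b)^2)
      bicv <- if (rss <= 1e-10 * tss) -Inf else
        n * log(rss / n) + (s + 1) * log(n)
      lbl <- if (s == 0) "(intercept only)" else
        paste(candidates[idx], collapse = " + ")
      rows[[length(rows) + 1]] <- data.frame(model = lbl, size = s, bic = bicv)
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$bic, df$size, df$model), ]
}
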