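#' Specify a linear model by response and predictor names
#'
#' Accepts either explicit arguments or a formula-like string
#' `"log_density ~ dhi_cum + bio1"`. An empty predictor set gives the
#' intercept-only model.
#'
#' @param response Response column name, or a `"y ~ x1 + x2"` string.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, predictors = NULL) {
  if (length(response) == 1L && grepl("~", response)) {
    f <- stats::as.formula(response)
    response <- all.vars(f[[2]])
    predictors <- if (identical(deparse(f[[3]]), "1")) character(0) else all.vars(f[[3]])
  }
  predictors <- as.character(predictors %||% character(0))
  if (anyDuplicated(predictors)) {
    stop("duplicated predictors: ",
         paste(unique(predictors[duplicated(predictors)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(response = response, predictors = predictors),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  rhs <- if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1"
  paste(x$response, "~", rhs)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n")
  invisible(x)
}

spec_formula <- function(spec) stats::as.formula(format(spec))

bic_from_rss <- function(n, rss, k, tss) {
  # n*ln(RSS/n) + k*ln(n), up to the usual model-independent constant;
  # an (essentially) exact fit is flagged as -Inf so rankings fall back to
  # model size rather than floating-point noise in a zero RSS.
  if (is_exact_fit(rss, tss)) return(-Inf)
  n * log(rss / n) + k * log(n)
}

is_exact_fit <- function(rss, tss) {
  rss <= 1e-10 * max(tss, .Machine$double.eps)
}

#' Fit an ordinary least-squares model
#'
#' Wraps `stats::lm` and returns the fit summaries used throughout model
#' selection: RSS, R2, adjusted R2, RMSE and BIC
#' (`n log(RSS/n) + k log(n)`, `k` = predictors + intercept).
#'
#' @param table Data frame holding the response and predictor columns.
#' @param spec A [model_spec()] or `"y ~ x1 + x2"` string.
#' @param rmse_denom RMSE denominator: `"n"` (default, a predictive-accuracy
#'   summary) or `"df"` (residual degrees of freedom).
#' @return An object of class `dhi_fit` with elements `spec`, `coefficients`,
#'   `se`, `rss`, `tss`, `n`, `p`, `r2`, `r2_adj`, `rmse`, `bic`, `fitted`,
#'   `residuals`, `df_residual`.
#' @export
fit_ols <- function(table, spec, rmse_denom = c("n", "df")) {
  rmse_denom <- match.arg(rmse_denom)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  need <- c(spec$response, spec$predictors)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table)
  p <- length(spec$predictors)
  if (n <= p + 1L) {
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  }
  fit <- stats::lm(spec_formula(spec), data = table)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  y <- table[[spec$response]]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2_adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  rmse <- sqrt(rss / if (rmse_denom == "n") n else (n - p - 1))
  structure(list(
    spec = spec,
    coefficients = cf,
    se = suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
    rss = rss, tss = tss, n = n, p = p,
    r2 = r2, r2_adj = r2_adj, rmse = rmse,
    bic = bic_from_rss(n, rss, p + 1L, tss),
    fitted = stats::fitted(fit),
    residuals = res,
    df_residual = n - p - 1L
  ), class = "dhi_fit")
}

#' @export
print.dhi_fit <- function(x, ...) {
  cat("<dhi_fit>", format(x$spec), "\n")
  cat(sprintf("  n = %d, R2_adj = %.3f, RMSE = %.3f, BIC = %.2f\n",
              x$n, x$r2_adj, x$rmse, x$bic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Bayesian Information Criterion of a fit
#'
#' `n log(RSS/n) + k log(n)` with `k` counting the intercept; lower is
#' better. Absolute values depend on this convention, so comparisons should
#' use BIC differences. An exact fit (RSS ~ 0) is `-Inf`.
#'
#' @param fit A `dhi_fit` from [fit_ols()].
#' @return A single number.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "dhi_fit"))
  fit$bic
}

subset_label <- function(vars) {
  if (length(vars) == 0L) "(intercept only)" else paste(vars, collapse = " + ")
}

#' Exhaustive best-subsets regression ranked by BIC
#'
#' Fits every subset of the candidate predictors up to `max_size` (the
#' intercept is always included) and ranks models by BIC; ties (including
#' exact fits, flagged `-Inf`) are broken by fewer predictors, then by the
#' alphabetical model label, so the ranking is deterministic.
#'
#' @param table Data frame with response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor names.
#' @param max_size Largest subset size to enumerate.
#' @param rmse_denom Passed to the per-model summaries (see [fit_ols()]).
#' @return A `subset_search` object: data frame
#'   `(rank, model, size, bic, delta_bic, r2, r2_adj, rmse)` sorted by rank,
#'   with the per-model predictor sets in `attr(, "predictor_sets")`.
#' @export
best_subsets <- function(table, response, candidates,
                         max_size = length(candidates),
                         rmse_denom = c("n", "df")) {
  rmse_denom <- match.arg(rmse_denom)
  miss <- setdiff(c(response, candidates), names(table))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(max_size <= length(candidates), max_size >= 0)
  y <- as.numeric(table[[response]])
  X <- as.matrix(table[candidates])
  storage.mode(X) <- "double"
  n <- length(y)
  if (n <= max_size + 1L) {
    stop("need n > max_size + 1 observations", call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  sets <- list()
  for (s in 0:max_size) {
    if (s == 0L) {
      sets <- c(sets, list(integer(0)))
    } else {
      cmb <- utils::combn(length(candidates), s)
      sets <- c(sets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    }
  }
  rows <- lapply(sets, function(idx) {
    Xs <- cbind(`(Intercept)` = 1, X[, idx, drop = FALSE])
    f <- stats::lm.fit(Xs, y)
    rss <- sum(f$residuals^2)
    p <- length(idx)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    data.frame(
      model = subset_label(candidates[idx]),
      size = p,
      bic = bic_from_rss(n, rss, p + 1L, tss),
      r2 = r2,
      r2_adj = if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_,
      rmse = sqrt(rss / if (rmse_denom == "n") n else (n - p - 1))
    )
  })
  df <- do.call(rbind, rows)
  ord <- order(df$bic, df$size, df$model)
  df <- df[ord, , drop = FALSE]
  sets <- lapply(sets[ord], function(idx) candidates[idx])
  best <- df$bic[1]
  df$delta_bic <- if (is.finite(best)) df$bic - best else
    ifelse(is.finite(df$bic), Inf, 0)
  df <- data.frame(rank = seq_len(nrow(df)),
                   df[c("model", "size", "bic", "delta_bic",
                        "r2", "r2_adj", "rmse")])
  rownames(df) <- NULL
  structure(df, class = c("subset_search", "data.frame"),
            response = response, candidates = candidates,
            predictor_sets = sets)
}

#' @export
print.subset_search <- function(x, n = 10, ...) {
  cat("<subset_search> response:", attr(x, "response"), "--",
      nrow(x), "models\n")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Predictors of the top-ranked subset model
#'
#' @param search A `subset_search` from [best_subsets()].
#' @param rank Rank to extract (1 = best).
#' @return Character vector of predictor names.
#' @export
top_model <- function(search, rank = 1) {
  stopifnot(inherits(search, "subset_search"))
  attr(search, "predictor_sets")[[rank]]
}

#' Screen candidate predictors for collinearity
#'
#' Computes the full Pearson correlation matrix, then clusters the
#' candidates by average-linkage hierarchical clustering on the distance
#' `1 - rho^2` (squared Spearman correlation). Within each cluster whose
#' members are mutually similar above `threshold` (on the rho^2 scale), all
#' but one representative are dropped; the representative is the first
#' cluster member in `prefer`, falling back to candidate order.
#'
#' @param table Data frame with the candidate columns.
#' @param candidates Character vector (>= 2) of column names.
#' @param threshold Similarity threshold on squared Spearman correlation at
#'   which variables are considered redundant (default 0.5).
#' @param prefer Optional character vector of variables to favour as
#'   cluster representatives.
#' @return A `collinearity_screen` list: `pearson`, `spearman_sq`, `tree`
#'   (an `hclust`, `NULL` for 2 candidates), `clusters` (named integer
#'   vector), `retained`, `dropped`.
#' @export
screen_collinearity <- function(table, candidates, threshold = 0.5,
                                prefer = NULL) {
  stopifnot(length(candidates) >= 2L)
  miss <- setdiff(candidates, names(table))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[candidates])
  sds <- apply(X, 2, stats::sd)
  if (any(!(sds > 0))) {
    stop("constant column(s) with undefined correlation: ",
         paste(candidates[!(sds > 0)], collapse = ", "), call. = FALSE)
  }
  pearson <- stats::cor(X)
  sp2 <- stats::cor(X, method = "spearman")^2
  tree <- NULL
  if (length(candidates) > 2L) {
    d <- stats::as.dist(1 - sp2)
    tree <- stats::hclust(d, method = "average")
    clusters <- stats::cutree(tree, h = 1 - threshold)
  } else {
    clusters <- if (sp2[1, 2] >= threshold) c(1L, 1L) else c(1L, 2L)
    names(clusters) <- candidates
  }
  pref_order <- c(intersect(prefer %||% character(0), candidates), candidates)
  retained <- vapply(unique(clusters), function(cl) {
    members <- names(clusters)[clusters == cl]
    pref_order[pref_order %in% members][1]
  }, character(1))
  retained <- candidates[candidates %in% retained]
  structure(list(pearson = pearson, spearman_sq = sp2, tree = tree,
                 clusters = clusters, retained = retained,
                 dropped = setdiff(candidates, retained),
                 threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen>", length(x$clusters), "candidates,",
      length(unique(x$clusters)), "clusters at rho^2 >=", x$threshold, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j`
#' on all the others (with intercept). Perfectly collinear predictors give
#' `Inf`.
#'
#' @param table Data frame with the predictor columns.
#' @param predictors Character vector (>= 2) of column names.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(table, predictors) {
  stopifnot(length(predictors) >= 2L)
  miss <- setdiff(predictors, names(table))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[predictors])
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n <= length(predictors) + 1L) {
    stop("need n > |predictors| + 1 observations", call. = FALSE)
  }
  out <- vapply(seq_along(predictors), function(j) {
    yj <- X[, j]
    Xo <- cbind(1, X[, -j, drop = FALSE])
    f <- stats::lm.fit(Xo, yj)
    rss <- sum(f$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- predictors
  out
}

#' Drop predictors from a model until all VIFs fall below a limit
#'
#' Iteratively removes the predictor with the largest VIF while any VIF is
#' at or above `limit`, refitting after each removal; each removal is
#' reported via `message()`.
#'
#' @param table Model table.
#' @param spec A [model_spec()] (or formula string) for the starting model.
#' @param limit VIF threshold (default 10).
#' @return List with the final `spec`, `fit` ([fit_ols()]), `vif` of the
#'   final predictors (`NULL` if < 2 remain) and `dropped` in removal order.
#' @export
vif_refine <- function(table, spec, limit = 10) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  dropped <- character(0)
  preds <- spec$predictors
  while (length(preds) >= 2L) {
    v <- vif(table, preds)
    if (max(v) < limit) break
    worst <- names(v)[which.max(v)]
    message("vif_refine: dropping '", worst, "' (VIF = ",
            format(v[[worst]], digits = 4), " >= ", limit, ")")
    dropped <- c(dropped, worst)
    preds <- setdiff(preds, worst)
  }
  final <- model_spec(spec$response, preds)
  list(spec = final,
       fit = fit_ols(table, final),
       vif = if (length(preds) >= 2L) vif(table, preds) else NULL,
       dropped = dropped)
}

#' Predictions and residuals of a fitted model on a table
#'
#' @param fit A `dhi_fit`.
#' @param table Data frame holding the fit's predictor and response columns
#'   (and optionally `region_id`, carried through).
#' @return Data frame `(region_id?, observed, predicted, residual)`.
#' @export
predict_residuals <- function(fit, table) {
  stopifnot(inherits(fit, "dhi_fit"))
  miss <- setdiff(c(fit$spec$response, fit$spec$predictors), names(table))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(1, as.matrix(table[fit$spec$predictors]))
  pred <- as.numeric(X %*% fit$coefficients)
  obs <- table[[fit$spec$response]]
  out <- data.frame(observed = obs, predicted = pred, residual = obs - pred)
  if ("region_id" %in% names(table)) {
    out <- cbind(region_id = table$region_id, out)
  }
  out
}
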