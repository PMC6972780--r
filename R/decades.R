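#' Refit one model specification on several decade tables
#'
#' @param tables Named list of per-decade design tables with identical
#'   region sets.
#' @param spec A [model_spec()] (or formula string) fitted independently to
#'   each table.
#' @param ... Passed to [fit_ols()].
#' @return Named list of `dhi_fit` objects, one per table.
#' @export
fit_decades <- function(tables, spec, ...) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  ids <- lapply(tables, function(t) sort(t$region_id))
  for (i in seq_along(tables)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      stop("decade tables do not share the same region set", call. = FALSE)
    }
  }
  lapply(tables, fit_ols, spec = spec, ...)
}

#' Stack decade tables into one pooled table with a period label
#'
#' @inheritParams fit_decades
#' @return One data frame with an added `period` column (the list names).
#' @export
stack_decades <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  do.call(rbind, lapply(names(tables), function(nm) {
    cbind(tables[[nm]][setdiff(names(tables[[nm]]), "period")],
          period = nm, stringsAsFactors = FALSE)
  }))
}

#' Extra-sum-of-squares F test between two decades
#'
#' Compares a reduced model with common coefficients across the two groups
#' against a full model with group-specific coefficients:
#' `F = ((RSS_red - RSS_full) / df1) / (RSS_full / df2)`. With
#' `test = "joint"` (default) the full model frees both the intercept and
#' all slopes (`df1 = p + 1`); with `test = "slopes"` the reduced model
#' already carries group-specific intercepts, so only the slopes are tested
#' (`df1 = p`). An exactly fitting full model is reported as `F = Inf`,
#' `p = 0` with `exact_fit = TRUE`.
#'
#' @param pooled Pooled table from [stack_decades()] (or any table with a
#'   group column).
#' @param spec Model specification shared by the groups.
#' @param pair Character vector of the two group labels to compare.
#' @param group_col Name of the group column (default `"period"`).
#' @param test `"joint"` or `"slopes"`.
#' @return An `extra_ss_test` list: `pair`, `test`, `F`, `df1`, `df2`,
#'   `p_value`, `rss_full`, `rss_reduced`, `exact_fit`.
#' @export
extra_ss_test <- function(pooled, spec, pair, group_col = "period",
                          test = c("joint", "slopes")) {
  test <- match.arg(test)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  stopifnot(length(pair) == 2L, group_col %in% names(pooled))
  sub <- pooled[pooled[[group_col]] %in% pair, , drop = FALSE]
  g <- factor(sub[[group_col]], levels = sort(pair))
  if (any(table(g) == 0L)) {
    stop("group(s) absent from pooled table: ",
         paste(pair[!(pair %in% sub[[group_col]])], collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(c(spec$response, spec$predictors), names(sub))
  if (length(miss)) {
    stop("columns absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(sub[[spec$response]])
  X <- as.matrix(sub[spec$predictors])
  storage.mode(X) <- "double"
  n <- length(y)
  p <- ncol(X)
  # full model: separate intercept and slopes per group
  rss_full <- 0
  for (lev in levels(g)) {
    sel <- g == lev
    f <- stats::lm.fit(cbind(1, X[sel, , drop = FALSE]), y[sel])
    rss_full <- rss_full + sum(f$residuals^2)
  }
  k_full <- 2L * (p + 1L)
  df2 <- n - k_full
  if (df2 <= 0L) stop("no residual degrees of freedom in the full model",
                      call. = FALSE)
  if (test == "joint") {
    Xr <- cbind(1, X)
  } else {
    Xr <- cbind(stats::model.matrix(~g), X)
  }
  rss_red <- sum(stats::lm.fit(Xr, y)$residuals^2)
  df1 <- k_full - ncol(Xr)
  tss <- sum((y - mean(y))^2)
  exact <- is_exact_fit(rss_full, tss)
  if (exact) {
    Fv <- Inf
    pv <- 0
  } else {
    Fv <- ((rss_red - rss_full) / df1) / (rss_full / df2)
    Fv <- max(Fv, 0)
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(list(pair = sort(pair), test = test, F = Fv,
                 df1 = df1, df2 = df2, p_value = pv,
                 rss_full = rss_full, rss_reduced = rss_red,
                 exact_fit = exact),
            class = "extra_ss_test")
}

#' @export
print.extra_ss_test <- function(x, ...) {
  cat("<extra_ss_test> ", paste(x$pair, collapse = " vs "),
      " (", x$test, ")\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g%s\n", x$df1, x$df2, x$F,
              x$p_value, if (x$exact_fit) " [exact full-model fit]" else ""))
  invisible(x)
}

#' Pairwise decade comparison of one model
#'
#' Fits `spec` to each decade table and runs [extra_ss_test()] for every
#' pair of decades.
#'
#' @inheritParams fit_decades
#' @param test Passed to [extra_ss_test()].
#' @return A `decade_comparison` list: `fits` (per decade) and `tests`
#'   (data frame `pair_a, pair_b, F, df1, df2, p_value`).
#' @export
decade_comparison <- function(tables, spec, test = c("joint", "slopes")) {
  test <- match.arg(test)
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  fits <- fit_decades(tables, spec)
  pooled <- stack_decades(tables)
  prs <- utils::combn(names(tables), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    t <- extra_ss_test(pooled, spec, prs[, j], test = test)
    data.frame(pair_a = prs[1, j], pair_b = prs[2, j], F = t$F,
               df1 = t$df1, df2 = t$df2, p_value = t$p_value)
  }))
  structure(list(fits = fits, tests = tests, spec = spec, test = test),
            class = "decade_comparison")
}

#' @export
print.decade_comparison <- function(x, ...) {
  cat("<decade_comparison>", format(x$spec), "\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-12s R2_adj = %.3f, RMSE = %.3f\n", nm, f$r2_adj, f$rmse))
  }
  print(x$tests, digits = 4)
  invisible(x)
}
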