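make_decade_tables <- function(beta, sigma, seed, n = 62,
                               slopes = list(NULL, NULL, NULL)) {
  set.seed(seed)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  labs <- names(decade_years())
  tabs <- lapply(seq_along(labs), function(i) {
    b <- slopes[[i]] %||% beta
    y <- b[1] + X %*% b[-1] + rnorm(n, 0, sigma)
    data.frame(region_id = seq_len(n), a = X[, "a"], b = X[, "b"],
               log_density = as.numeric(y))
  })
  names(tabs) <- labs
  tabs
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("identical decade tables give identical fits and F = 0, p = 1", {
  tabs <- make_decade_tables(c(1, 0.5, -0.2), 0.3, seed = 51)
  tabs[["1991-2000"]] <- tabs[["1981-1990"]]
  fits <- fit_decades(tabs, "log_density ~ a + b")
  expect_equal(fits[[1]]$coefficients, fits[[2]]$coefficients)
  pooled <- stack_decades(tabs)
  t0 <- extra_ss_test(pooled, "log_density ~ a + b",
                      c("1981-1990", "1991-2000"))
  expect_equal(t0$F, 0)
  expect_equal(t0$p_value, 1)
})

test_that("an exactly interacting no-noise pair overflows to F = Inf, p = 0", {
  # two groups, slopes 1 vs 2, zero noise: the full model is exact
  pooled <- data.frame(
    x = rep(c(1, 2, 3), 2),
    log_density = c(1, 2, 3, 2, 4, 6),
    period = rep(c("A", "B"), each = 3))
  t1 <- extra_ss_test(pooled, "log_density ~ x", c("A", "B"))
  expect_true(t1$exact_fit)
  expect_identical(t1$F, Inf)
  expect_equal(t1$p_value, 0)
})

test_that("extra SS F matches explicit design-matrix least squares", {
  set.seed(53)
  n <- 20
  pooled <- data.frame(
    a = rnorm(n), b = rnorm(n),
    period = rep(c("P1", "P2"), each = n / 2))
  pooled$log_density <- 1 + pooled$a - 0.5 * pooled$b +
    0.4 * (pooled$period == "P2") + rnorm(n, 0, 0.5)
  got <- extra_ss_test(pooled, "log_density ~ a + b", c("P1", "P2"))
  # independent route: base-R anova on nested lm fits
  full <- lm(log_density ~ period * (a + b), data = pooled)
  red <- lm(log_density ~ a + b, data = pooled)
  an <- anova(red, full)
  expect_equal(got$F, an$F[2], tolerance = 1e-10)
  expect_equal(got$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(got$df1, an$Df[2])

  # slope-only variant against its own nested pair
  got_s <- extra_ss_test(pooled, "log_density ~ a + b", c("P1", "P2"),
                         test = "slopes")
  red_s <- lm(log_density ~ period + a + b, data = pooled)
  an_s <- anova(red_s, full)
  expect_equal(got_s$F, an_s$F[2], tolerance = 1e-10)
  expect_equal(got_s$p_value, an_s$`Pr(>F)`[2], tolerance = 1e-10)

  # symmetric in the pair's labelling
  swapped <- extra_ss_test(pooled, "log_density ~ a + b", c("P2", "P1"))
  expect_equal(swapped$F, got$F)
})

test_that("same-coefficient decades rarely reject; a halved slope is detected", {
  labs <- names(decade_years())[1:2]
  null_rej <- 0
  power_rej <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    tabs <- make_decade_tables(c(2, 0.5, -0.3), 0.1, seed = 100 + s)
    pooled <- stack_decades(tabs[labs])
    if (extra_ss_test(pooled, "log_density ~ a + b", labs)$p_value < 0.05) {
      null_rej <- null_rej + 1
    }
    tabs2 <- make_decade_tables(
      c(2, 0.5, -0.3), 0.05, seed = 200 + s,
      slopes = list(NULL, c(2, 0.25, -0.3), NULL))
    pooled2 <- stack_decades(tabs2[labs])
    if (extra_ss_test(pooled2, "log_density ~ a + b", labs)$p_value < 0.05) {
      power_rej <- power_rej + 1
    }
  }
  expect_lte(null_rej / n_seeds, 0.2)
  expect_gte(power_rej / n_seeds, 0.9)
})

test_that("decade_comparison reports all pairs and per-decade summaries", {
  tabs <- make_decade_tables(c(1, 1, 0), 0.2, seed = 61)
  cmp <- decade_comparison(tabs, "log_density ~ a + b")
  expect_equal(nrow(cmp$tests), 3L)
  expect_true(all(cmp$tests$p_value >= 0 & cmp$tests$p_value <= 1))
  expect_true(all(cmp$tests$F >= 0))
  expect_named(cmp$fits, names(decade_years()))
  expect_error(
    fit_decades(list(A = tabs[[1]], B = tabs[[2]][-1, ]), "log_density ~ a"),
    "region set")
})
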