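test_that("fit_ols reproduces hand-solved normal equations on a toy set", {
  toy <- data.frame(x = c(0, 1, 2, 3, 4), y = c(1.1, 1.9, 3.2, 3.8, 5.1))
  X <- cbind(1, toy$x)
  b_hand <- solve(crossprod(X), crossprod(X, toy$y))
  fit <- fit_ols(toy, model_spec("y", "x"))
  expect_equal(unname(fit$coefficients), as.numeric(b_hand))
  expect_equal(fit$rss, sum((toy$y - X %*% b_hand)^2))
  expect_equal(fit$rmse, sqrt(fit$rss / 5))
  expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * 4 / 3)

  # exactly linear response: perfect fit
  lin <- data.frame(x = 1:6, y = 2 + 3 * (1:6))
  pf <- fit_ols(lin, "y ~ x")
  expect_equal(pf$r2, 1)
  expect_equal(pf$r2_adj, 1)
  expect_equal(pf$rss, 0, tolerance = 1e-20)
  expect_identical(pf$bic, -Inf)

  # permuting rows changes nothing
  set.seed(2)
  tab <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  tab$y <- 1 + tab$x1 - 2 * tab$x2 + rnorm(20)
  f1 <- fit_ols(tab, "y ~ x1 + x2")
  f2 <- fit_ols(tab[sample(20), ], "y ~ x1 + x2")
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$bic, f2$bic)

  # rank deficiency errors, naming the collinear column
  tab$x3 <- tab$x1
  expect_error(fit_ols(tab, "y ~ x1 + x3"), "collinear.*x3")
  expect_error(fit_ols(tab[1:3, ], "y ~ x1 + x2"), "n > p \\+ 1")
})

test_that("BIC pays exactly ln(n) for a predictor that leaves RSS unchanged", {
  set.seed(4)
  n <- 40
  tab <- data.frame(x1 = rnorm(n))
  tab$y <- 2 + tab$x1 + rnorm(n)
  # orthogonalized second predictor with zero extra fit by construction:
  # compare analytically via the bic definition instead
  f1 <- fit_ols(tab, "y ~ x1")
  k1 <- 2
  expect_equal(bic(f1), n * log(f1$rss / n) + k1 * log(n))
  # delta-BIC is invariant to adding a constant to both models' BIC
  f0 <- fit_ols(tab, model_spec("y", character(0)))
  d <- bic(f0) - bic(f1)
  expect_equal((bic(f0) + 5) - (bic(f1) + 5), d)
})

test_that("best_subsets enumerates 2^k models and matches the enumeration oracle", {
  set.seed(11)
  tab2 <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  tab2$y <- tab2$x1 + rnorm(30)
  bs2 <- best_subsets(tab2, "y", c("x1", "x2"))
  expect_equal(nrow(bs2), 4L)

  # noiseless response from x1 alone: {x1} wins outright
  tab0 <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  tab0$y <- 3 - 2 * tab0$x1
  bs0 <- best_subsets(tab0, "y", c("x1", "x2"))
  expect_equal(bs0$model[1], "x1")
  expect_identical(bs0$bic[1], -Inf)
  expect_equal(top_model(bs0), "x1")

  # 8 candidates, max size 4: full ranking equals the independent oracle
  vars <- paste0("v", 1:8)
  tab8 <- random_design(62, vars, seed = 13)
  tab8$y <- 1 + 0.8 * tab8$v2 - 0.5 * tab8$v5 + rnorm(62, 0, 0.4)
  bs8 <- best_subsets(tab8, "y", vars, max_size = 4)
  oracle <- subsets_enum_oracle(tab8, "y", vars, 4)
  expect_equal(nrow(bs8), nrow(oracle))
  expect_equal(bs8$model, oracle$model)
  expect_equal(bs8$bic, oracle$bic, tolerance = 1e-10)
  # the top model never has higher BIC than any enumerated model
  expect_true(all(bs8$bic[1] <= bs8$bic))
  expect_equal(bs8$delta_bic[1], 0)

  expect_error(best_subsets(tab8, "y", c(vars, "nope")), "absent")
})

test_that("adding a pure-noise predictor lowers adjusted R2 but not R2", {
  set.seed(19)
  tab <- data.frame(x1 = rnorm(50))
  tab$y <- tab$x1 + rnorm(50)
  tab$junk <- rnorm(50)
  f1 <- fit_ols(tab, "y ~ x1")
  f2 <- fit_ols(tab, "y ~ x1 + junk")
  expect_gte(f2$r2, f1$r2)
  expect_lt(f2$r2_adj - f1$r2_adj, 0.02)  # penalty bites unless junk helps
})

test_that("collinearity screen clusters duplicates and keeps independents", {
  set.seed(23)
  tab <- data.frame(x1 = rnorm(40))
  tab$x2 <- 2 * tab$x1
  tab$x3 <- rnorm(40)
  scr <- screen_collinearity(tab, c("x1", "x2", "x3"))
  expect_equal(scr$pearson["x1", "x2"], 1)
  expect_equal(scr$clusters[["x1"]], scr$clusters[["x2"]])
  expect_false(scr$clusters[["x3"]] == scr$clusters[["x1"]])
  expect_equal(scr$retained, c("x1", "x3"))
  expect_equal(scr$dropped, "x2")
  # preference nominates the representative
  scr2 <- screen_collinearity(tab, c("x1", "x2", "x3"), prefer = "x2")
  expect_equal(scr2$retained, c("x2", "x3"))

  # independent normals at large n: no clustering at threshold 0.5
  big <- random_design(400, paste0("z", 1:5), seed = 29)
  scr3 <- screen_collinearity(big, paste0("z", 1:5))
  expect_equal(length(unique(scr3$clusters)), 5L)
  expect_equal(scr3$retained, paste0("z", 1:5))

  tab$flat <- 1
  expect_error(screen_collinearity(tab, c("x1", "flat")), "constant")
})

test_that("VIF follows 1/(1 - R2_j), with exact values on constructed data", {
  # orthogonal predictors -> VIF 1
  n <- 64
  t_seq <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  orth <- data.frame(a = sin(t_seq), b = cos(t_seq))
  v <- vif(orth, c("a", "b"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)

  # a pair with sample correlation exactly 0.89 -> VIF = 1/(1 - 0.89^2)
  set.seed(31)
  x <- rnorm(62)
  e <- rnorm(62)
  x <- (x - mean(x)) / sd(x)
  e <- resid(lm(e ~ x))
  e <- e / sd(e)
  tab <- data.frame(p1 = x, p2 = 0.89 * x + sqrt(1 - 0.89^2) * e)
  expect_equal(cor(tab$p1, tab$p2), 0.89, tolerance = 1e-12)
  v2 <- vif(tab, c("p1", "p2"))
  expect_equal(unname(v2), rep(1 / (1 - 0.89^2), 2), tolerance = 1e-6)
  expect_equal(unname(v2)[1], 4.81, tolerance = 0.01)

  # duplicated column -> infinite VIF
  dup <- data.frame(q1 = rnorm(20))
  dup$q2 <- dup$q1
  expect_equal(unname(vif(dup, c("q1", "q2"))), c(Inf, Inf))
})

test_that("VIF agrees with an established implementation", {
  skip_if_not_installed("car")
  tab <- random_design(62, c("a", "b", "c"), seed = 37)
  tab$b <- tab$a * 0.7 + tab$b * 0.5
  tab$y <- tab$a + rnorm(62)
  ours <- vif(tab, c("a", "b", "c"))
  theirs <- car::vif(lm(y ~ a + b + c, data = tab))
  expect_equal(unname(ours), unname(theirs[c("a", "b", "c")]),
               tolerance = 1e-10)
})

test_that("vif_refine drops offenders above the limit and reports them", {
  set.seed(41)
  tab <- data.frame(x1 = rnorm(50), x3 = rnorm(50))
  tab$x2 <- tab$x1 + rnorm(50, 0, 1e-6)  # near-duplicate
  tab$y <- tab$x1 + tab$x3 + rnorm(50)
  expect_message(
    ref <- vif_refine(tab, model_spec("y", c("x1", "x2", "x3")), limit = 10),
    "dropping")
  expect_equal(length(ref$dropped), 1L)
  expect_true(ref$dropped %in% c("x1", "x2"))
  expect_true(all(ref$vif < 10))
  # a clean model is untouched
  ref2 <- vif_refine(tab, model_spec("y", c("x1", "x3")), limit = 10)
  expect_equal(ref2$dropped, character(0))
})

test_that("residuals sum to zero on training data and are stable to row order", {
  set.seed(43)
  tab <- random_design(30, c("x1", "x2"), seed = 43)
  tab$y <- 2 + tab$x1 - tab$x2 + rnorm(30)
  names(tab)[1] <- "region_id"
  fit <- fit_ols(tab, "y ~ x1 + x2")
  pr <- predict_residuals(fit, tab)
  expect_equal(sum(pr$residual), 0, tolerance = 1e-10)
  worst1 <- pr$region_id[which.max(pr$residual)]
  perm <- tab[sample(30), ]
  pr2 <- predict_residuals(fit, perm)
  expect_equal(pr2$region_id[which.max(pr2$residual)], worst1)
  # perfect fit -> all residuals zero
  lin <- data.frame(x1 = 1:8, y = 3 * (1:8))
  prl <- predict_residuals(fit_ols(lin, "y ~ x1"), lin)
  expect_equal(prl$residual, rep(0, 8), tolerance = 1e-10)
})

test_that("the empirical semivariogram matches its definition", {
  # two points, residuals 1 and 3: single pair, gamma = 2
  sv <- residual_semivariogram(c(1, 3), data.frame(x = c(0, 0), y = c(0, 1)),
                               n_bins = 1)
  expect_equal(sv$semivariance, 2)
  expect_equal(sv$n_pairs, 1L)

  # constant residuals: zero in every occupied bin
  set.seed(47)
  coords <- data.frame(x = runif(12), y = runif(12))
  svc <- residual_semivariogram(rep(0.7, 12), coords, n_bins = 5)
  expect_true(all(svc$semivariance[svc$n_pairs > 0] == 0))
  expect_equal(sum(svc$n_pairs), 12 * 11 / 2)

  # iid residuals at many points: no distance trend
  set.seed(49)
  coords2 <- data.frame(x = runif(150), y = runif(150))
  z <- rnorm(150)
  sv2 <- residual_semivariogram(z, coords2, n_bins = 8)
  occupied <- sv2$n_pairs > 20
  trend <- lm(semivariance ~ lag_mid, data = sv2[occupied, ])
  expect_gt(summary(trend)$coefficients["lag_mid", "Pr(>|t|)"], 0.01)

  expect_error(
    residual_semivariogram(c(1, 2), data.frame(x = c(1, 1), y = c(2, 2))),
    "coincident")
})
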