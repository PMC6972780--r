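test_that("composite_fpar pools the cross-year (and paired-period) median", {
  # single pixel, 2 periods x 2 years with known values
  arr <- array(NA_real_, c(1, 1, 2, 2))
  arr[1, 1, 1, ] <- c(0.4, 0.6)
  arr[1, 1, 2, ] <- c(0.2, 0.9)
  st <- fpar_stack(arr, period_length_days = 8)
  cs <- composite_fpar(st, target_period_days = 8)
  expect_equal(cs$values[1, 1, 1], 0.5)
  expect_equal(cs$values[1, 1, 2], 0.55)

  # three years, odd median
  arr3 <- array(c(0.2, 0.5, 0.9), c(1, 1, 1, 3))
  expect_equal(
    composite_fpar(fpar_stack(arr3), target_period_days = 8)$values[1, 1, 1],
    0.5)

  # missing values are omitted; a singleton survives, an empty cell is NA
  arr_na <- array(c(0.4, NA), c(1, 1, 1, 2))
  expect_equal(
    composite_fpar(fpar_stack(arr_na), target_period_days = 8)$values[1, 1, 1],
    0.4)
  arr_all_na <- array(NA_real_, c(1, 1, 1, 2))
  expect_true(is.na(
    composite_fpar(fpar_stack(arr_all_na),
                   target_period_days = 8)$values[1, 1, 1]))

  # pairing 8-day periods into a 16-day composite pools both periods
  arr2 <- array(NA_real_, c(1, 1, 2, 1))
  arr2[1, 1, , 1] <- c(0.1, 0.5)
  cs16 <- composite_fpar(fpar_stack(arr2), target_period_days = 16)
  expect_equal(dim(cs16$values)[3], 1L)
  expect_equal(cs16$values[1, 1, 1], 0.3)

  expect_error(composite_fpar(fpar_stack(arr2), target_period_days = 12),
               "multiple")
})

test_that("cumulative DHI sums available composite values", {
  mk <- function(v) {
    arr <- array(v, c(1, 1, length(v), 1))
    composite_fpar(fpar_stack(arr), target_period_days = 8)
  }
  expect_equal(cumulative_dhi(mk(c(0.1, 0.2, 0.3)))[1, 1], 0.6)
  expect_equal(cumulative_dhi(mk(rep(0, 7)))[1, 1], 0)
  expect_equal(cumulative_dhi(mk(rep(0.5, 46)))[1, 1], 23)
  expect_equal(cumulative_dhi(mk(c(0.2, NA, 0.3)))[1, 1], 0.5)
})

test_that("minimum DHI takes the annual low and zero-fills darkness gaps", {
  mk <- function(v) {
    arr <- array(v, c(1, 1, length(v), 1))
    composite_fpar(fpar_stack(arr), target_period_days = 8)
  }
  expect_equal(minimum_dhi(mk(c(0.3, 0.1, 0.5)))[1, 1], 0.1)
  expect_equal(minimum_dhi(mk(rep(0.7, 5)))[1, 1], 0.7)
  # a winter gap sets the minimum to zero when darkness_fill is on
  expect_equal(minimum_dhi(mk(c(NA, 0.4, 0.6)))[1, 1], 0)
  expect_equal(minimum_dhi(mk(c(NA, 0.4, 0.6)), darkness_fill = FALSE)[1, 1],
               0.4)
})

test_that("variation DHI is the coefficient of variation and scale-free", {
  mk <- function(v) {
    arr <- array(v, c(1, 1, length(v), 1))
    composite_fpar(fpar_stack(arr), target_period_days = 8)
  }
  expect_equal(variation_dhi(mk(c(0.1, 0.2, 0.3)))[1, 1], 0.5)
  expect_equal(variation_dhi(mk(rep(0.4, 6)))[1, 1], 0)
  # scaling every value by c > 0 leaves the CV unchanged
  v <- c(0.12, 0.5, 0.33, 0.9)
  expect_equal(variation_dhi(mk(v))[1, 1], variation_dhi(mk(v / 3))[1, 1])
  # zero-mean pixels are flagged missing, not an error
  expect_true(is.na(variation_dhi(mk(c(0, 0, 0)))[1, 1]))
  # population-sd option uses the n denominator
  expect_equal(variation_dhi(mk(c(0.1, 0.3)), sd_denom = "population")[1, 1],
               0.1 / 0.2)
})

test_that("compute_dhi matches closed-form values on a noiseless sinusoid", {
  P <- 8
  st <- sinusoid_stack(P = P, m = 0.5, a = 0.3)
  tau <- (seq_len(P) - 0.5) / P
  v <- 0.5 + 0.3 * cos(2 * pi * (tau - 0.54))
  dhi <- compute_dhi(st, target_period_days = 8)
  expect_equal(dhi$cumulative[1, 1], sum(v))
  expect_equal(dhi$minimum[2, 2], min(v))
  expect_equal(dhi$variation[1, 2], sd(v) / mean(v))
})

test_that("compute_dhi equals a nested-loop oracle on random gappy stacks", {
  set.seed(42)
  for (rep in 1:5) {
    arr <- array(runif(3 * 3 * 4 * 2), c(3, 3, 4, 2))
    arr[sample(length(arr), 6)] <- NA
    st <- fpar_stack(arr, period_length_days = 8)
    got <- compute_dhi(st, target_period_days = 8)
    want <- dhi_loop_oracle(arr)
    expect_equal(got$cumulative, want$cumulative)
    expect_equal(got$minimum, want$minimum)
    expect_equal(got$variation, want$variation)
  }
})

test_that("DHIs are invariant to year ordering and NA-propagating", {
  set.seed(7)
  arr <- array(runif(2 * 2 * 4 * 3), c(2, 2, 4, 3))
  arr[1, 1, , ] <- NA  # an all-missing pixel
  st1 <- fpar_stack(arr)
  st2 <- fpar_stack(arr[, , , c(3, 1, 2), drop = FALSE])
  d1 <- compute_dhi(st1, target_period_days = 8)
  d2 <- compute_dhi(st2, target_period_days = 8)
  expect_equal(d1$cumulative, d2$cumulative)
  expect_equal(d1$variation, d2$variation)
  expect_true(all(is.na(c(d1$cumulative[1, 1], d1$minimum[1, 1],
                          d1$variation[1, 1]))))
})

test_that("gap-free pixels satisfy minimum <= mean and cumulative = n * mean", {
  set.seed(9)
  arr <- array(runif(4 * 5 * 6 * 2), c(4, 5, 6, 2))
  dhi <- compute_dhi(fpar_stack(arr), target_period_days = 8)
  mean_comp <- dhi$cumulative / 6
  expect_true(all(dhi$minimum <= mean_comp + 1e-12))
  expect_true(all(dhi$variation >= 0))
})

test_that("fpar_stack rejects out-of-range values", {
  expect_error(fpar_stack(array(1.2, c(1, 1, 1, 1))), "0, 1")
  expect_error(fpar_stack(array(-0.1, c(1, 1, 1, 1))), "0, 1")
})
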