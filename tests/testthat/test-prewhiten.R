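test_that("max_order_bound follows ten-times-the-rate with a hard cap", {
  expect_identical(max_order_bound(1), 10L)
  expect_identical(max_order_bound(4), 40L)
  expect_identical(max_order_bound(0.01), 1L)
  expect_identical(max_order_bound(4, hard_cap = 25), 25L)
  expect_error(max_order_bound(0), "positive")
  expect_error(max_order_bound(-2), "positive")
})

test_that("compute_bic matches its closed form and is monotone in the penalty", {
  expect_equal(compute_bic(50, 100, 3), 100 * log(0.5) + 3 * log(100),
               tolerance = 1e-12)
  expect_equal(compute_bic(50, 100, 3), -55.4992, tolerance = 1e-4)
  # same rss, higher order -> strictly larger BIC
  expect_lt(compute_bic(50, 100, 1), compute_bic(50, 100, 2))
  # halving rss at fixed order lowers BIC
  expect_lt(compute_bic(25, 100, 3), compute_bic(50, 100, 3))
  expect_error(compute_bic(0, 100, 1), "degenerate")
  expect_error(compute_bic(-1, 100, 1), "degenerate")
  expect_error(compute_bic(10, 3, 5), "order")
})

test_that("fit_ar selects order 0 on white noise and reduces variance", {
  set.seed(101)
  y <- rnorm(3000)
  m <- fit_ar(y, max_order = 10, fs = 1)
  ok <- m$order == 0L ||
    abs(var(m$innovations) - var(y)) / var(y) < 0.01
  expect_true(ok)
  expect_lte(var(m$innovations) * (length(m$innovations) - 1),
             var(y) * (length(y) - 1) + 1e-8)
  # structural invariants
  expect_length(m$coeffs, m$order)
  expect_length(m$innovations, length(y) - m$order)
  expect_gte(m$noise_variance, 0)
  expect_identical(which.min(m$bic_trace) - 1L, m$order)
})

test_that("fit_ar recovers AR coefficients, agreeing with Yule-Walker", {
  errs_cls <- matrix(NA_real_, 200, 2)
  errs_yw <- matrix(NA_real_, 200, 2)
  for (i in 1:200) {
    y <- gen_ar(3000, c(0.5, 0.3), seed = 500 + i)
    m <- fit_ar(y, max_order = 5, fs = 1)
    cf <- c(m$coeffs, numeric(2))[1:2]
    errs_cls[i, ] <- abs(cf - c(0.5, 0.3))
    # independent oracle: Yule-Walker on sample autocovariances
    g <- acf(y, lag.max = 2, type = "covariance", plot = FALSE)$acf[, 1, 1]
    yw <- solve(matrix(c(g[1], g[2], g[2], g[1]), 2), g[2:3])
    errs_yw[i, ] <- abs(yw - c(0.5, 0.3))
  }
  expect_lt(mean(errs_cls), 0.05)
  expect_lt(mean(errs_yw), 0.05)
  # the two estimators agree closely with each other
  expect_lt(mean(abs(errs_cls - errs_yw)), 0.02)
  # AR(1) variant
  errs1 <- vapply(1:200, function(i) {
    y <- gen_ar(3000, 0.8, seed = 900 + i)
    m <- fit_ar(y, max_order = 5, fs = 1)
    abs(c(m$coeffs, 0)[1] - 0.8)
  }, numeric(1))
  expect_lt(mean(errs1), 0.05)
})

test_that("fit_ar picks orders around 10-20 for hemodynamic data at 5 Hz", {
  ords <- vapply(1:5, function(s) {
    pair <- gen_hemo_pair(3000, fs = 5, seed = 400 + s)
    fit_ar(pair$a)$order
  }, integer(1))
  expect_true(all(ords >= 10 & ords <= 20))
})

test_that("fit_ar rejects degenerate inputs", {
  expect_error(fit_ar(rep(1, 100), max_order = 5, fs = 1), "constant")
  expect_error(fit_ar(rnorm(50), max_order = 20, fs = 1), "short")
})

test_that("apply_ar_filter inverts the generating recursion", {
  # order-0 model returns the mean-centered input
  set.seed(7)
  y <- rnorm(100) + 5
  m0 <- fit_ar(y, max_order = 0, fs = 1)
  out <- apply_ar_filter(y, m0, fs = 1)
  expect_equal(as.numeric(out), y - mean(y), tolerance = 1e-12)
  # forward-simulate AR(1) with a = 0.8, then invert with the true model:
  # the generating noise is recovered to numerical precision (up to the
  # constant from mean-centering)
  set.seed(8)
  eps <- rnorm(400)
  x <- as.numeric(stats::filter(eps, 0.8, method = "recursive"))
  truth <- structure(list(coeffs = 0.8, order = 1L, fs = 1), class = "fc_ar")
  rec <- apply_ar_filter(x, truth, fs = 1)
  expect_equal(as.numeric(rec), eps[-1] - 0.2 * mean(x), tolerance = 1e-12)
  # and the BIC fit finds the right order with a close coefficient
  m <- fit_ar(x, max_order = 3, fs = 1)
  expect_identical(m$order, 1L)
  expect_gt(cor(as.numeric(apply_ar_filter(x, m, fs = 1)), eps[-1]), 0.99)
  expect_error(apply_ar_filter(rnorm(5), structure(list(order = 10L),
                                                   class = "fc_ar"), fs = 1),
               "order")
})

test_that("BIC-whitened hemodynamic innovations are serially flat", {
  nbad <- vapply(1:5, function(s) {
    pair <- gen_hemo_pair(3000, fs = 4, seed = 40 + s)
    m <- fit_ar(pair$a)
    n <- length(m$innovations)
    ac <- acf(m$innovations, lag.max = 20, plot = FALSE)$acf[-1]
    sum(abs(ac) > 2 / sqrt(n))
  }, numeric(1))
  # pooled over 100 (replicate, lag) pairs, ~95% should sit inside +/-2/sqrt(n)
  expect_lt(sum(nbad) / (5 * 20), 0.10)
})

test_that("prewhiten_pair aligns innovations and is symmetric on identical input", {
  set.seed(21)
  y <- as.numeric(stats::filter(rnorm(500), c(0.4, 0.2), method = "recursive"))
  a <- fc_ts(y, fs = 2); b <- fc_ts(y, fs = 2)
  pp <- prewhiten_pair(a, b, max_order = 6)
  expect_identical(as.numeric(pp$a), as.numeric(pp$b))
  expect_identical(length(pp$a), length(pp$b))
  expect_error(prewhiten_pair(fc_ts(rnorm(100), 1), fc_ts(rnorm(101), 1)),
               "lengths")
  expect_error(prewhiten_pair(fc_ts(rnorm(100), 1), fc_ts(rnorm(100), 2)),
               "rates")
})

test_that("prewhitened white pairs pass a portmanteau whiteness test", {
  pass <- vapply(1:200, function(s) {
    set.seed(s)
    pp <- prewhiten_pair(fc_ts(rnorm(600), 1), fc_ts(rnorm(600), 1),
                         max_order = 6)
    min(Box.test(as.numeric(pp$a), lag = 20, type = "Ljung-Box")$p.value,
        Box.test(as.numeric(pp$b), lag = 20, type = "Ljung-Box")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("whiteness holds across simulated AR processes", {
  frac_in <- vapply(1:200, function(i) {
    y <- gen_ar(800, c(0.6, -0.2), seed = 1500 + i)
    m <- fit_ar(y, max_order = 6, fs = 1)
    n <- length(m$innovations)
    ac <- acf(m$innovations, lag.max = 20, plot = FALSE)$acf[-1]
    mean(abs(ac) <= 2 / sqrt(n))
  }, numeric(1))
  expect_gte(mean(frac_in), 0.90)
})

test_that("fit_ar is deterministic", {
  y <- gen_ar(1000, 0.5, seed = 3)
  m1 <- fit_ar(y, max_order = 8, fs = 1)
  m2 <- fit_ar(y, max_order = 8, fs = 1)
  expect_identical(m1$coeffs, m2$coeffs)
  expect_identical(m1$innovations, m2$innovations)
})
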