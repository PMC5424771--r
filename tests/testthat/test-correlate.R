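test_that("pearson_correlation matches hand computation and cor.test", {
  a <- fc_ts(c(1, 2, 3, 4), 1); b <- fc_ts(c(1, 2, 3, 5), 1)
  fit <- pearson_correlation(a, b)
  expect_equal(fit$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(fit$r, 0.9827, tolerance = 1e-4)
  set.seed(51)
  x <- rnorm(300); y <- 0.3 * x + rnorm(300)
  fit <- pearson_correlation(x, y, fs = 1)
  ct <- cor.test(x, y)
  expect_equal(fit$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(fit$pvalue, ct$p.value, tolerance = 1e-12)
  ident <- pearson_correlation(fc_ts(x, 1), fc_ts(x, 1))
  expect_identical(ident$r, 1)
  expect_identical(ident$pvalue, 0)
  expect_error(pearson_correlation(rep(1, 10), rnorm(10), fs = 1), "variance")
})

test_that("correlation_pvalue inverts the t transform", {
  expect_identical(correlation_pvalue(0, 100), 1)
  expect_equal(correlation_pvalue(0.0358, 2998), 0.05, tolerance = 0.002)
  expect_identical(correlation_pvalue(1, 50), 0)
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, correlation_pvalue, numeric(1), dof = 40)
  expect_true(all(diff(ps) < 0))          # strictly decreasing in |r|
  expect_error(correlation_pvalue(1.2, 10), "<= 1")
  expect_error(correlation_pvalue(0.3, 0), "positive")
})

test_that("lowpass_correlation enforces Nyquist and boosts in-band signal", {
  a <- fc_ts(rnorm(200), fs = 1)
  expect_error(lowpass_correlation(a, a, cutoff = 0.6), "fs/2")
  set.seed(52)
  x <- rnorm(400)
  xf <- fc_ts(x, fs = 1)
  expect_equal(lowpass_correlation(xf, xf, cutoff = 0.1)$r, 1, tolerance = 1e-9)
  # shared slow sinusoid buried in independent white noise: filtering helps
  fs <- 2; n <- 2000; t <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 0.05 * t)
  a <- fc_ts(s + rnorm(n, sd = 1.5), fs)
  b <- fc_ts(s + rnorm(n, sd = 1.5), fs)
  expect_gt(lowpass_correlation(a, b, cutoff = 0.1)$r,
            pearson_correlation(a, b)$r)
})

test_that("robust estimator reduces to Pearson under unit weights", {
  set.seed(53)
  for (i in 1:100) {
    n <- 50 + sample(200, 1)
    x <- rnorm(n)
    y <- runif(1, -0.9, 0.9) * x + rnorm(n) * runif(1, 0.5, 2) + runif(1, -5, 5)
    fit <- robust_correlation(fc_ts(x, 1), fc_ts(y, 1), prewhiten = FALSE,
                              preweight = FALSE, kappa = Inf)
    expect_equal(fit$r, cor(x, y), tolerance = 1e-10)
    # the sqrt(b1 * a1) identity against the explicit OLS slopes
    b1 <- cov(x, y) / var(y); a1 <- cov(x, y) / var(x)
    expect_equal(abs(fit$r), sqrt(b1 * a1), tolerance = 1e-10)
  }
})

test_that("combined estimate is symmetric, bounded, and signed correctly", {
  set.seed(54)
  x <- rnorm(500)
  a <- fc_ts(x, 2)
  expect_equal(robust_correlation(a, a, prewhiten = FALSE)$r, 1)
  neg <- robust_correlation(a, fc_ts(-x, 2), prewhiten = FALSE)
  expect_equal(neg$r, -1)
  expect_lt(neg$pvalue, 1e-10)
  for (s in 1:5) {
    pair <- simulate_neural_pair(800, rho = 0.3, seed = 60 + s, fs = 2)
    cont <- inject_motion(pair, 0.05, 10, seed = 60 + s)
    f_ab <- robust_correlation(cont$a, cont$b)
    f_ba <- robust_correlation(cont$b, cont$a)
    expect_equal(f_ab$r, f_ba$r, tolerance = 1e-12)
    expect_lte(abs(f_ab$r), 1)
    expect_gte(f_ab$pvalue, 0)
    expect_lte(f_ab$pvalue, 1)
    expect_lte(f_ab$dof, f_ab$n_used - 2)
  }
})

test_that("full estimator recovers a true correlation of 0.5", {
  for (s in 1:3) {
    pair <- simulate_neural_pair(3000, rho = 0.5, seed = 70 + s, fs = 4)
    fit <- robust_correlation(pair$a, pair$b, prewhiten = TRUE,
                              preweight = TRUE)
    expect_lt(abs(fit$r - 0.5), 0.04)
  }
})

test_that("robust estimates are stable across motion scenarios", {
  est <- function(scenario) {
    vals <- vapply(1:5, function(s) {
      pair <- simulate_neural_pair(3000, rho = 0.5, seed = 80 + s, fs = 1)
      pair <- switch(scenario,
                     none = pair,
                     unshared = inject_motion(pair, 0.05, 10,
                                              shared_times = FALSE),
                     shared = inject_motion(pair, 0.05, 10,
                                            shared_times = TRUE))
      robust_correlation(pair$a, pair$b, prewhiten = FALSE)$r
    }, numeric(1))
    mean(vals)
  }
  naive <- function(scenario) {
    vals <- vapply(1:5, function(s) {
      pair <- simulate_neural_pair(3000, rho = 0.5, seed = 80 + s, fs = 1)
      pair <- switch(scenario,
                     none = pair,
                     unshared = inject_motion(pair, 0.05, 10,
                                              shared_times = FALSE),
                     shared = inject_motion(pair, 0.05, 10,
                                            shared_times = TRUE))
      pearson_correlation(pair$a, pair$b)$r
    }, numeric(1))
    mean(vals)
  }
  r_clean <- est("none"); r_un <- est("unshared"); r_sh <- est("shared")
  # the three robust estimates agree within Monte-Carlo error
  expect_lt(max(abs(c(r_clean - r_un, r_clean - r_sh, r_un - r_sh))), 0.08)
  # while the naive ones are dragged around by the artifacts
  expect_gt(max(abs(c(naive("none") - naive("unshared"),
                      naive("none") - naive("shared")))), 0.10)
})

test_that("fc_correlate dispatches every comparison model", {
  pair <- gen_hemo_pair(600, fs = 4, rho = 0.4, seed = 90)
  for (m in c("COR", "LPF-COR", "W-COR", "AR-COR", "AR-W-COR")) {
    fit <- fc_correlate(pair$a, pair$b, method = m)
    expect_s3_class(fit, "fc_cor")
    expect_lte(abs(fit$r), 1)
    expect_true(fit$pvalue >= 0 && fit$pvalue <= 1)
  }
  expect_error(fc_correlate(pair$a, pair$b, method = "nope"))
  # methods as printed objects
  expect_output(print(fc_correlate(pair$a, pair$b, "AR-W-COR")), "AR-W-COR")
  expect_output(print(summary(fc_correlate(pair$a, pair$b, "W-COR"))),
                "directional")
})
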