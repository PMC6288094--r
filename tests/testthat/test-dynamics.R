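test_that("largest-patch series computes RSmax and centred fluctuations", {
  cens <- list(make_census(c(60, 30, 10), 2000),
               make_census(c(40, 40, 20), 2001),
               make_census(c(90, 5, 5), 2002))
  s <- build_series(cens)
  expect_equal(s$rs_max, c(0.6, 0.4, 0.9))
  expect_equal(mean(s$delta_rs_max), 0, tolerance = 1e-12)
  expect_equal(s$delta_s_max, s$s_max - mean(s$s_max))
  one <- build_series(list(make_census(100, 2000), make_census(100, 2001),
                           make_census(100, 2002)))
  expect_equal(one$rs_max, c(1, 1, 1))
  expect_error(build_series(cens[1:2]), "at least 3")
})

test_that("an empty census is reported with its year", {
  cens <- list(make_census(c(10, 5), 2000), make_census(c(10, 5), 2001),
               make_census(c(10, 5), 2002))
  cens[[2]]$total_forest <- 0
  expect_error(build_series(cens), "2001")
})

test_that("sample skewness matches direct moments and is shift invariant", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  v <- c(1, 1, 1, 10)
  expect_equal(sample_skewness(v), skew_oracle(v))
  expect_gt(sample_skewness(v), 0)
  set.seed(31)
  x <- rnorm(50)
  expect_equal(sample_skewness(x), sample_skewness(x - mean(x)))
  expect_warning(sk <- sample_skewness(rep(2, 5)), "zero variance")
  expect_true(is.na(sk))
  # on a series object, skewness of rs_max equals skewness of delta_rs_max
  cens <- lapply(2000:2007, function(y)
    make_census(sample(5:60, 4), y))
  s <- build_series(cens)
  expect_equal(sample_skewness(s), skew_oracle(s$rs_max))
})

test_that("fluctuation fits go undetermined on short series, exponential on gaussian noise", {
  # 16 annual points rarely discriminate the tail class: the typical
  # outcome over seeded replicates is "undetermined"
  set.seed(32)
  outcomes <- replicate(10, {
    v <- rnorm(16, 0, 0.02)
    fit_fluctuations(v - mean(v))$best_model
  })
  expect_gt(mean(outcomes == "undetermined"), 0.5)
  g <- rnorm(5000)
  fg <- fit_fluctuations(g - mean(g))
  expect_false(fg$selection$best_model == "powerlaw")
  expect_error(fit_fluctuations(rep(0, 16)), "degenerate|equal")
  expect_error(fit_fluctuations(rnorm(5)), "at least 8")
})

test_that("quantile slopes match an exact pinball-loss oracle", {
  set.seed(33)
  t <- 1:16
  y <- 0.2 * t + rnorm(16)
  for (tau in c(0.1, 0.5, 0.9)) {
    rq_slope <- unname(coef(suppressWarnings(quantreg::rq(y ~ t, tau = tau)))[2])
    expect_equal(rq_slope, pinball_fit_oracle(t, y, tau)$slope,
                 tolerance = 1e-8)
  }
})

test_that("variance trend detects spread growth and stays quiet on noise", {
  # noiseless linear series: both quantile slopes equal the true slope
  y <- 2 * (1:12)
  tr <- variance_trend(y, seed = 1, reps = 200)
  expect_equal(unname(tr$slopes), c(2, 2), tolerance = 1e-8)
  # growing spread, long series
  set.seed(34)
  v <- rnorm(200, 0, seq(0.5, 3, length.out = 200))
  tr2 <- variance_trend(v - mean(v), seed = 2, reps = 300)
  expect_equal(tr2$direction, "increase")
  # constant series: no significant trend
  tr3 <- variance_trend(rep(0, 16) + c(rep(c(-1e-6, 1e-6), 8)), seed = 3,
                        reps = 200)
  expect_equal(tr3$direction, "NS")
  expect_error(variance_trend(rnorm(5)), "at least 8")
  # determinism under a fixed seed
  set.seed(35); v4 <- rnorm(16)
  a <- variance_trend(v4, seed = 7, reps = 200)
  b <- variance_trend(v4, seed = 7, reps = 200)
  expect_identical(a$ci, b$ci)
})

test_that("median quantile regression recovers a known slope within its band", {
  set.seed(36)
  t <- 1:60
  y <- 1.5 * t + rnorm(60, 0, 2)
  tr <- variance_trend(y, quantiles = c(0.5, 0.9), years = t, seed = 4,
                       reps = 400)
  expect_lt(abs(tr$slopes[1] - 1.5), 0.2)
})

test_that("dip statistic matches exact closed-form anchors", {
  expect_equal(dip_statistic(c(0, 1)), 0.25, tolerance = 1e-8)
  for (n in c(10, 25, 50)) {
    expect_equal(dip_statistic(1:n), 1 / (2 * n), tolerance = 1e-8)
    expect_equal(dip_statistic((1:n)^2), 1 / (2 * n), tolerance = 1e-8)
  }
  # two tight pairs: convex branch must hand the slope ordering across the
  # gap, giving dip = (1/4) * gap / (gap + eps)
  eps <- 0.01
  expect_equal(dip_statistic(c(0, eps, 1, 1 + eps)),
               0.25 * (1 - eps) / ((1 - eps) + eps), tolerance = 1e-6)
  set.seed(37)
  cl <- c(rnorm(250, 0, 0.01), rnorm(250, 10, 0.01))
  expect_gt(dip_statistic(cl), 0.24)
  # bounds and invariance
  for (i in 1:5) {
    x <- rnorm(100)
    d <- dip_statistic(x)
    expect_gte(d, 1 / 200); expect_lte(d, 0.25)
    expect_equal(dip_statistic(3 * x + 5), d, tolerance = 1e-9)
  }
})

test_that("dip test separates unimodal from bimodal samples", {
  set.seed(40)
  u <- runif(300)
  expect_gt(dip_test(u, reps = 500, seed = 5)$p_value, 0.1)
  b <- c(rnorm(250), rnorm(250, 6))
  res <- dip_test(b, reps = 500, seed = 5)
  expect_lt(res$p_value, 0.05)
  expect_error(dip_test(c(1, 2, 3)), "at least 4")
})

test_that("dip p-values are uniform under the uniform null", {
  set.seed(39)
  ps <- vapply(1:500, function(i) {
    dip_test(runif(40), reps = 150)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
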