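test_that("power-law MLE matches the closed form exactly", {
  x <- rep(exp(1), 4)
  expect_equal(unname(fit_powerlaw(x, 1)$params["alpha"]), 2)
  set.seed(21)
  for (i in 1:10) {
    x <- powerlaw_sample(200, runif(1, 1.5, 3.5), x_min = runif(1, 0.5, 4))
    xm <- min(x)
    fit <- fit_powerlaw(x, xm)
    expect_equal(unname(fit$params["alpha"]),
                 1 + length(x) / sum(log(x / xm)))
  }
  s <- powerlaw_sample(10000, 2.05, 1, seed = 22)
  ah <- unname(fit_powerlaw(s, 1)$params["alpha"])
  expect_gt(ah, 2.00); expect_lt(ah, 2.10)
  expect_error(fit_powerlaw(rep(2, 5), 2), "degenerate")
  expect_error(fit_powerlaw(3, 1), "at least 2")
})

test_that("x_min scan recovers the scaling changepoint", {
  x <- c(powerlaw_sample(4000, 2, 5, seed = 11), runif(4000, 1, 5))
  set.seed(11)
  est <- estimate_xmin(x)
  expect_gt(est$x_min, 3.2); expect_lt(est$x_min, 6.8)
  x2 <- powerlaw_sample(4000, 2.2, 1, seed = 12)
  expect_equal(estimate_xmin(x2)$x_min, min(x2))
  expect_error(estimate_xmin(c(1, 2, 3, 4, 5)), "insufficient")
})

test_that("alternative fits behave at their boundaries and beat the power law on their own data", {
  pl <- powerlaw_sample(3000, 2.05, 1, seed = 13)
  fc <- fit_powerlaw_cutoff(pl, 1)
  fp <- fit_powerlaw(pl, 1)
  expect_gte(fc$loglik, fp$loglik)          # nesting, always
  expect_lt(fc$loglik - fp$loglik, 3)       # lambda -> 0 limit
  expect_lt(fc$params[["lambda"]], 1e-3)

  set.seed(14)
  e <- 1 + rexp(5000, 1)
  expect_gt(fit_exponential(e, 1)$loglik, fit_powerlaw(e, 1)$loglik)
  expect_equal(unname(fit_exponential(e, 1)$params["lambda"]),
               1 / (mean(e) - 1))

  set.seed(15)
  ln <- rlnorm(500, -2, 0.5)                # unconstrained mu would be < 0
  expect_equal(unname(fit_lognormal(ln, min(ln))$params["mu"]), 0)
})

test_that("AICc weights and likelihood-ratio tests follow their definitions", {
  mk <- function(model, lp, k) {
    structure(list(model = model, params = stats::setNames(rep(1, k), letters[1:k]),
                   x_min = 1, n_tail = length(lp), loglik = sum(lp),
                   loglik_pointwise = lp, ks = 0.1, n_par = k,
                   converged = TRUE), class = "fit_result")
  }
  set.seed(16)
  base <- rnorm(200, -2, 0.3)
  sel_eq <- select_model(list(powerlaw = mk("powerlaw", base, 1),
                              exponential = mk("exponential", base, 1)))
  expect_equal(unname(sel_eq$weights), c(0.5, 0.5))
  # Delta AICc of 10 <=> weight ratio exp(5)
  shifted <- base + 5 / length(base)
  sel10 <- select_model(list(powerlaw = mk("powerlaw", shifted, 1),
                             exponential = mk("exponential", base, 1)))
  expect_equal(unname(sel10$weights["powerlaw"] / sel10$weights["exponential"]),
               exp(5), tolerance = 1e-8)
  expect_equal(sel10$best_model, "powerlaw")
  expect_error(select_model(list(powerlaw = mk("powerlaw", rnorm(2), 1),
                                 lognormal = mk("lognormal", rnorm(2), 2))),
               "AICc undefined")
})

test_that("a large power-law sample is selected and separated from the exponential", {
  x <- powerlaw_sample(5000, 2.05, 1, seed = 17)
  res <- fit_patch_models(x, x_min = 1)
  expect_equal(res$selection$best_model, "powerlaw")
  lrt <- res$selection$lrt
  p_exp <- lrt$p_value[lrt$comparison == "powerlaw_vs_exponential"]
  expect_lt(p_exp, 0.05)
  expect_gt(lrt$R[lrt$comparison == "powerlaw_vs_exponential"], 0)
})

test_that("fitted tail CDFs track the analytic power-law CDF", {
  x <- powerlaw_sample(10000, 2.5, 2, seed = 18)
  fit <- fit_powerlaw(x, 2)
  expect_lt(fit$ks, 0.02)
  sx <- sort(x)
  n <- length(sx)
  Fo <- ppl_oracle(sx, fit$params[["alpha"]], 2)
  expect_equal(max(abs(Fo - seq_len(n) / n), abs(Fo - (seq_len(n) - 1) / n)),
               fit$ks, tolerance = 1e-6)
})

test_that("BCa bootstrap is seeded, reproducible and flags degeneracy", {
  expect_identical(formals(bootstrap_ci)$replications, 10000L)
  x <- powerlaw_sample(300, 2.2, 1, seed = 19)
  ci1 <- bootstrap_ci(x, replications = 499, seed = 42, x_min = 1)
  ci2 <- bootstrap_ci(x, replications = 499, seed = 42, x_min = 1)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
  expect_error(bootstrap_ci(x, replications = 50), ">= 199")
  # degenerate resampling statistic -> zero width, flagged
  const <- bca_int <- fragcrit:::bca_interval(1, rep(1, 500), rep(1, 10))
  expect_true(const$degenerate)
  expect_equal(const$lower, const$upper)
})

test_that("upper incomplete gamma matches quadrature for negative shapes", {
  for (a in c(-0.3, -1.05, -2.6)) for (z in c(0.05, 0.8, 4)) {
    num <- integrate(function(u) exp((a - 1) * log(u) - u), z, Inf,
                     rel.tol = 1e-11)$value
    expect_equal(upper_inc_gamma(a, z), num, tolerance = 1e-7)
  }
})
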