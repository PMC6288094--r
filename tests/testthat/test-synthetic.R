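test_that("percolation lattices hit their degenerate and seeded-determinism contracts", {
  expect_equal(sum(percolation_lattice(32, 0, seed = 1)$mask), 0)
  full <- percolation_lattice(32, 1, seed = 1)
  cen <- label_patches(full)
  expect_equal(cen$n_patches, 1L)
  expect_equal(cen$s_max, 32^2)
  a <- percolation_lattice(64, 0.4, seed = 9)
  b <- percolation_lattice(64, 0.4, seed = 9)
  expect_identical(a$mask, b$mask)
  set.seed(52)
  dens <- mean(percolation_lattice(256, 0.35)$mask)
  expect_equal(dens, 0.35, tolerance = 0.02)
})

test_that("percolation phase behaviour brackets the critical occupancy", {
  rs <- function(p, seed) label_patches(percolation_lattice(512, p, seed))$rs_max
  set.seed(53)
  expect_lt(rs(0.30, 101), 0.1)
  expect_gt(rs(0.55, 102), 0.6)
  # spanning probability is monotone across the transition
  ps <- vapply(c(0.30, 0.41, 0.55), function(p)
    spanning_probability(128, p, reps = 20, seed = 7), numeric(1))
  expect_true(ps[1] < 0.2 && ps[3] > 0.8)
  expect_true(ps[1] <= ps[2] && ps[2] <= ps[3])
})

test_that("the stored critical occupancy fixture matches the scan interface", {
  pc <- stored_critical_occupancy()
  expect_gt(pc$p_c, 0.35); expect_lt(pc$p_c, 0.45)
  expect_true(all(diff(pc$by_L) > -0.02))  # estimates settle with L
  expect_equal(pc$seed, 1)
})

test_that("power-law sampler matches its analytic CDF and moments", {
  expect_error(powerlaw_sample(10, 1), "alpha")
  x <- powerlaw_sample(10000, 3, 2, seed = 54)
  expect_gte(min(x), 2)
  expect_equal(mean(x), 2 * (3 - 1) / (3 - 2), tolerance = 0.1)
  s <- sort(powerlaw_sample(10000, 2.3, 1, seed = 55))
  ks <- max(abs(ppl_oracle(s, 2.3, 1) - seq_along(s) / length(s)))
  expect_lt(ks, 0.02)
})

test_that("tail samplers feed their own fitters consistently", {
  x <- tail_sample("powerlaw_cutoff", 3000, 1,
                   list(alpha = 1.5, lambda = 0.05), seed = 56)
  fit <- fit_powerlaw_cutoff(x, 1)
  expect_equal(unname(fit$params["alpha"]), 1.5, tolerance = 0.15)
  expect_equal(unname(fit$params["lambda"]), 0.05, tolerance = 0.1)
  y <- tail_sample("lognormal", 4000, 1, list(mu = 1, sigma = 0.8), seed = 57)
  fl <- fit_lognormal(y, 1)
  expect_equal(unname(fl$params["mu"]), 1, tolerance = 0.15)
})

test_that("contact process decays without colonisation and persists above threshold", {
  snaps <- contact_process(48, lambda = 0, years = 12, init_density = 0.4,
                           seed = 58)
  dens <- vapply(snaps, function(s) mean(s$mask), numeric(1))
  expect_true(all(diff(dens) <= 0))
  expect_lt(dens[length(dens)], 0.01)
  # well below threshold: extinction on a small lattice
  low <- contact_process(48, lambda = 0.5, years = 40, init_density = 0.4,
                         seed = 59)
  expect_equal(mean(low[[40]]$mask), 0)
  # well above: quasi-stationary density near the mean-field anchor 1 - 1/lambda
  hi <- contact_process(64, lambda = 8, years = 30, init_density = 0.5,
                        seed = 60)
  d_hi <- mean(vapply(hi[20:30], function(s) mean(s$mask), numeric(1)))
  mf <- 1 - 1 / 8
  expect_gt(d_hi, mf - 0.2); expect_lt(d_hi, mf + 0.05)
  # seeded determinism
  r1 <- contact_process(32, 2, years = 5, seed = 61)
  r2 <- contact_process(32, 2, years = 5, seed = 61)
  expect_identical(r1[[5]]$mask, r2[[5]]$mask)
})

test_that("region fixtures land in their dynamical regimes", {
  sup <- region_fixture("supercritical", years = 6, L = 128, seed = 62,
                        thresholds = 40)
  rs <- vapply(sup$censuses[[1]], function(cn) cn$rs_max, numeric(1))
  expect_true(all(rs > 0.6))
  sub <- region_fixture("subcritical", years = 6, L = 128, seed = 63,
                        thresholds = 40)
  rs_sub <- vapply(sub$censuses[[1]], function(cn) cn$rs_max, numeric(1))
  expect_true(all(rs_sub < 0.3))
  tr <- region_fixture("transition", years = 16, L = 96, seed = 64,
                       thresholds = 30)
  expect_lt(tr$occupancy[16], tr$occupancy[1])
  # thresholds in 20-40 recover the same latent forest mask
  multi <- region_fixture("supercritical", years = 3, L = 64, seed = 65)
  sizes20 <- multi$censuses[["t20"]][[1]]$sizes
  sizes40 <- multi$censuses[["t40"]][[1]]$sizes
  expect_equal(sort(sizes20), sort(sizes40))
})

test_that("critical exponents cluster near the universality value at modest L", {
  pc <- stored_critical_occupancy()$p_c
  a <- critical_alpha(pc, L = 512, reps = 4, seed = 66)
  expect_true(all(a > 1.7 & a < 2.4))
  expect_identical(critical_alpha(pc, L = 256, reps = 2, seed = 67),
                   critical_alpha(pc, L = 256, reps = 2, seed = 67))
})
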