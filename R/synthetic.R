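# Lattice simulators and samplers: site percolation, contact process,
# heavy-tail samplers, and multi-year region fixtures for end-to-end tests.

#' Random site-percolation landscape
#'
#' Each cell is occupied (forest) independently with probability `p`. With
#' Moore-neighbourhood patch connectivity the critical occupancy sits near
#' 0.407 (located by [critical_occupancy()], not hard-coded): below it the
#' landscape is fragmented, above it one patch dominates.
#'
#' @param L lattice side (>= 2).
#' @param p occupancy probability in \[0, 1\].
#' @param seed integer seed (optional; uses the current RNG state when
#'   `NULL`).
#' @param boundary `"open"` (bounded region, the empirical default) or
#'   `"periodic"` (simulator calibration).
#' @param region_id,year metadata for downstream plumbing.
#' @return a `binary_landscape`.
#' @export
percolation_lattice <- function(L, p, seed = NULL,
                                boundary = c("open", "periodic"),
                                region_id = "perc", year = NA_integer_) {
  boundary <- match.arg(boundary)
  stopifnot(L >= 2, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(runif(L * L) < p, L, L)
  land <- as_binary_landscape(mask, region_id = region_id, year = year)
  land$boundary <- boundary
  land
}

#' Does a patch span the lattice?
#'
#' A landscape percolates when one patch touches both opposite edges
#' (top-bottom or left-right).
#'
#' @param land a `binary_landscape` or logical matrix.
#' @return logical.
#' @export
spans_lattice <- function(land) {
  land <- as_binary_landscape(land)
  labels <- .ccl_label(land$mask, FALSE)
  top <- unique(labels[1, ]); bottom <- unique(labels[nrow(labels), ])
  left <- unique(labels[, 1]); right <- unique(labels[, ncol(labels)])
  top <- top[top > 0]; bottom <- bottom[bottom > 0]
  left <- left[left > 0]; right <- right[right > 0]
  length(intersect(top, bottom)) > 0 || length(intersect(left, right)) > 0
}

#' Spanning probability at a given occupancy
#'
#' @param L lattice side.
#' @param p occupancy.
#' @param reps replicate lattices.
#' @param seed integer seed.
#' @return fraction of replicates containing a spanning patch.
#' @export
spanning_probability <- function(L, p, reps = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(reps), function(i)
    spans_lattice(percolation_lattice(L, p)), logical(1)))
}

#' Locate the Moore-neighbourhood critical occupancy
#'
#' Bisection on the occupancy for a spanning probability of 0.5 at each
#' lattice size, followed by finite-size extrapolation: the 0.5-crossing
#' approaches the critical point as `p_c - c * L^(-1/nu)` with the 2D
#' percolation correlation-length exponent `nu = 4/3`, so a linear fit of
#' the per-L crossings against `L^(-3/4)` is extrapolated to infinite L.
#' This is the package's oracle for p_c; the value is never taken from
#' literature.
#'
#' @param L_values lattice sides, scanned in order; each refines the
#'   bracket left by the previous one.
#' @param reps spanning replicates per probe.
#' @param iters bisection iterations per lattice size.
#' @param seed integer seed.
#' @param bracket initial occupancy bracket.
#' @param extrapolate return the `L^(-3/4)` extrapolation (default); when
#'   `FALSE`, the crossing at the largest L.
#' @return list with `p_c`, `by_L` (per-size crossings), `seed`, `reps`.
#' @export
critical_occupancy <- function(L_values = c(256, 512, 1024), reps = 48L,
                               iters = 5L, seed = 1L,
                               bracket = c(0.30, 0.55), extrapolate = TRUE) {
  set.seed(seed)
  by_L <- numeric(0)
  lo <- bracket[1]; hi <- bracket[2]
  centre <- mean(bracket)
  for (L in L_values) {
    # coarse bisection to centre the probe grid
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      ps <- spanning_probability(L, mid, reps = 16L)
      if (ps < 0.5) lo <- mid else hi <- mid
    }
    centre <- (lo + hi) / 2
    # logistic fit of the spanning probability over a grid spanning the
    # finite-size transition window (width ~ L^(-3/4))
    half <- max(0.6 * L^(-3 / 4), 0.003)
    grid <- seq(centre - half, centre + half, length.out = 7)
    hits <- vapply(grid, function(p) {
      sum(vapply(seq_len(reps), function(i)
        spans_lattice(percolation_lattice(L, p)), logical(1)))
    }, numeric(1))
    fit <- suppressWarnings(
      stats::glm(cbind(hits, reps - hits) ~ grid, family = stats::binomial()))
    est <- unname(-coef(fit)[1] / coef(fit)[2])   # logit crossing at 0.5
    if (!is.finite(est) || abs(est - centre) > 2 * half) est <- centre
    by_L <- c(by_L, stats::setNames(est, paste0("L", L)))
    lo <- max(est - 2 * half, bracket[1]); hi <- min(est + 2 * half, bracket[2])
  }
  p_c <- if (extrapolate && length(L_values) >= 2L) {
    x <- L_values^(-3 / 4)
    unname(coef(lm(by_L ~ x))[1])
  } else {
    unname(by_L[length(by_L)])
  }
  list(p_c = p_c, by_L = by_L, seed = seed, reps = reps)
}

#' Stored critical occupancy (spanning-scan fixture)
#'
#' Reads the critical occupancy located once by [critical_occupancy()] and
#' shipped as a plain-text fixture (with its seed, lattice sizes and
#' replicate count) under `extdata/`.
#'
#' @return list with `p_c` and the scan metadata.
#' @export
stored_critical_occupancy <- function() {
  path <- system.file("extdata", "critical_occupancy.csv", package = "fragcrit")
  if (path == "") stop("critical occupancy fixture not installed")
  df <- read.table(path, header = TRUE, sep = ",")
  # the L = Inf row holds the finite-size extrapolation
  list(p_c = df$p_c[nrow(df)],
       by_L = stats::setNames(df$p_c[is.finite(df$L)],
                              paste0("L", df$L[is.finite(df$L)])),
       seed = df$seed[1], reps = df$reps[1])
}

#' Contact-process forest dynamics
#'
#' Two-state (forest / non-forest) lattice model: occupied sites go extinct
#' at rate 1, empty sites are colonised at rate `lambda` scaled by the
#' occupied fraction of their Moore neighbourhood. Updates are asynchronous
#' single-site attempts; one "year" is `L^2` attempts (a sweep). The model
#' has an absorbing empty state below a critical colonisation rate.
#'
#' @param L lattice side.
#' @param lambda colonisation rate (extinction rate normalised to 1).
#' @param years number of sweeps to run.
#' @param init_density initial occupancy.
#' @param seed integer seed.
#' @param periodic periodic boundaries (default, reduces finite-size bias).
#' @param record_every keep a snapshot every this many sweeps.
#' @return list of `binary_landscape` snapshots (year metadata = sweep
#'   index).
#' @export
contact_process <- function(L, lambda, years = 16L, init_density = 0.5,
                            seed = NULL, periodic = TRUE, record_every = 1L) {
  stopifnot(L >= 2, lambda >= 0, years >= 1)
  if (!is.null(seed)) set.seed(seed)
  init <- runif(L * L) < init_density
  snaps <- .contact_process_run(init, L, as.integer(years), lambda,
                                periodic, as.integer(record_every))
  per <- L * L
  n_snap <- length(snaps) / per
  lapply(seq_len(n_snap), function(i) {
    mask <- matrix(snaps[((i - 1) * per + 1):(i * per)], L, L)
    as_binary_landscape(mask, region_id = "cp", year = i * record_every)
  })
}

#' Inverse-CDF sampler for the continuous power law
#'
#' `x = x_min * (1 - u)^(-1/(alpha-1))`, `u ~ U(0, 1)`.
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param x_min lower bound.
#' @param seed integer seed.
#' @return numeric sample of size `n`.
#' @export
powerlaw_sample <- function(n, alpha, x_min = 1, seed = NULL) {
  if (alpha <= 1) stop("alpha must exceed 1")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x_min * (1 - runif(n))^(-1 / (alpha - 1))
}

#' Samplers for the four tail models
#'
#' Draws from the same tail densities the fitters use: power law (inverse
#' CDF), power law with exponential cut-off (rejection from the power law),
#' truncated log-normal (rejection above `x_min`), shifted exponential.
#' Used for model-selection power checks.
#'
#' @param model model name.
#' @param n sample size.
#' @param x_min tail lower bound.
#' @param params named parameters (`alpha`, `lambda`, `mu`, `sigma` as
#'   required).
#' @param seed integer seed.
#' @return numeric sample of size `n`.
#' @export
tail_sample <- function(model = c("powerlaw", "powerlaw_cutoff", "lognormal",
                                  "exponential"),
                        n, x_min = 1, params = list(), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  switch(model,
    powerlaw = powerlaw_sample(n, p$alpha, x_min),
    exponential = x_min + rexp(n, rate = p$lambda),
    lognormal = {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- rlnorm(2L * n, meanlog = p$mu, sdlog = p$sigma)
        out <- c(out, cand[cand >= x_min])
      }
      out[seq_len(n)]
    },
    powerlaw_cutoff = {
      # rejection: propose power law, accept with exp(-lambda (x - x_min))
      out <- numeric(0)
      while (length(out) < n) {
        cand <- powerlaw_sample(2L * n, p$alpha, x_min)
        keep <- runif(length(cand)) < exp(-p$lambda * (cand - x_min))
        out <- c(out, cand[keep])
      }
      out[seq_len(n)]
    })
}

#' Fitted cluster-size exponents at a given occupancy
#'
#' Generates replicate site-percolation lattices, extracts the
#' Moore-neighbourhood patch census and fits the continuous power law with
#' KS-estimated lower bound to the finite-cluster sizes. At the critical
#' occupancy the mean exponent recovers the isotropic-percolation
#' universality-class value (about 2.055 in two dimensions). Following
#' standard percolation practice the largest (incipient spanning) cluster is
#' excluded from the finite-cluster statistics, and periodic boundaries are
#' used to reduce finite-size bias; both are calibration defaults, not
#' choices made for empirical rasters.
#'
#' @param p occupancy probability.
#' @param L lattice side.
#' @param reps replicate lattices.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param drop_largest exclude the largest cluster from the census.
#' @param boundary `"periodic"` (default for calibration) or `"open"`.
#' @param max_candidates cap for the x_min scan (see [estimate_xmin()]).
#' @return numeric vector of fitted exponents, one per replicate.
#' @export
critical_alpha <- function(p, L = 2048L, reps = 10L, seed = 1L,
                           drop_largest = TRUE,
                           boundary = c("periodic", "open"),
                           max_candidates = 400L) {
  boundary <- match.arg(boundary)
  periodic <- boundary == "periodic"
  vapply(seq_len(reps), function(r) {
    land <- percolation_lattice(L, p, seed = seed + r, boundary = boundary)
    sizes <- label_patches(land, periodic = periodic)$sizes
    if (drop_largest && length(sizes) > 1L) sizes <- sizes[-which.max(sizes)]
    est <- estimate_xmin(sizes, max_candidates = max_candidates)
    unname(est$fit$params[["alpha"]])
  }, numeric(1))
}

# scenario definitions: occupancy path of the control parameter over years.
# Calibrated once on exploratory percolation runs and then frozen; see the
# methods vignette for the rationale.
scenario_occupancy <- function(regime, years, p_c, drift = NULL, noise = NULL) {
  base <- switch(regime,
    supercritical = list(from = 0.55, to = 0.55, sd = 0.005),
    subcritical = list(from = 0.30, to = 0.30, sd = 0.005),
    near_critical = list(from = p_c + 0.004, to = p_c + 0.004, sd = 0.004),
    transition = list(from = 0.50, to = p_c + 0.003, sd = 0.006),
    stop("unknown regime: ", regime))
  if (!is.null(drift)) base$to <- base$from + drift
  if (!is.null(noise)) base$sd <- noise
  p <- seq(base$from, base$to, length.out = years) + rnorm(years, 0, base$sd)
  pmin(pmax(p, 0.01), 0.99)
}

#' Multi-year synthetic region fixture
#'
#' Emulates a 16-year regional cover-raster series in a chosen dynamical
#' regime. Each year is a site-percolation landscape whose occupancy follows
#' the regime's path (`transition` ramps from the connected phase towards
#' the critical occupancy; `supercritical`/`subcritical`/`near_critical`
#' hold it fixed, with small year-to-year noise). Latent forest cells get
#' cover drawn from 45-100%, non-forest cells from 0-15%, so every threshold
#' in the standard 20-40% sweep recovers the same latent forest mask.
#' Censuses are produced through the raster pipeline ([census_sweep()]).
#'
#' @param regime one of `"subcritical"`, `"near_critical"`,
#'   `"supercritical"`, `"transition"`.
#' @param years series length (default 16, one landscape per year).
#' @param L lattice side.
#' @param seed integer seed.
#' @param thresholds cover thresholds for the censuses.
#' @param p_c critical occupancy used to anchor the regimes (defaults to the
#'   stored spanning-scan value).
#' @param drift,noise optional overrides of the regime's occupancy drift
#'   (total change over the series) and noise standard deviation.
#' @param region_id region label.
#' @return list with `years`, `occupancy`, `rasters` (yearly
#'   [cover_raster()]s) and `censuses` (per threshold, per year), plus the
#'   scenario metadata.
#' @export
region_fixture <- function(regime = c("transition", "supercritical",
                                      "subcritical", "near_critical"),
                           years = 16L, L = 256L, seed = 1L,
                           thresholds = c(20, 25, 30, 35, 40),
                           p_c = NULL, drift = NULL, noise = NULL,
                           region_id = regime) {
  regime <- match.arg(regime)
  if (years < 3L) stop("years must be >= 3")
  if (is.null(p_c)) {
    p_c <- tryCatch(stored_critical_occupancy()$p_c, error = function(e) 0.407)
  }
  set.seed(seed)
  occ <- scenario_occupancy(regime, years, p_c, drift, noise)
  yrs <- seq(2000L, by = 1L, length.out = years)
  rasters <- vector("list", years)
  for (i in seq_len(years)) {
    forest <- matrix(runif(L * L) < occ[i], L, L)
    cover <- matrix(runif(L * L, 0, 15), L, L)
    cover[forest] <- runif(sum(forest), 45, 100)
    rasters[[i]] <- cover_raster(round(cover), region_id = region_id,
                                 year = yrs[i])
  }
  censuses <- lapply(thresholds, function(th) {
    lapply(rasters, function(r) label_patches(binarize(r, th)))
  })
  names(censuses) <- paste0("t", thresholds)
  list(regime = regime, years = yrs, occupancy = occ, p_c = p_c,
       rasters = rasters, censuses = censuses, seed = seed, L = L,
       thresholds = thresholds)
}
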