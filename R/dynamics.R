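# Largest-patch time-series diagnostics: RSmax series, fluctuation
# distributions, variance trends via quantile regression, skewness and the
# Hartigan dip test for bimodality of RSmax.

#' Build the largest-patch series from yearly censuses
#'
#' Aligns yearly patch censuses (same region, same threshold) into the
#' largest-patch series: `s_max(t)`, total forest area, `rs_max(t) =
#' s_max / total`, and the centred fluctuation series
#' `delta_s_max(t) = s_max(t) - mean(s_max)` (same for `rs_max`).
#'
#' @param censuses list of `patch_census`, one per year.
#' @return a `largest_patch_series`.
#' @export
build_series <- function(censuses) {
  if (length(censuses) < 3L) stop("need at least 3 years of censuses")
  empty <- vapply(censuses, function(cn) cn$total_forest <= 0, logical(1))
  if (any(empty)) {
    yrs <- vapply(censuses[empty], function(cn) as.integer(cn$year), integer(1))
    stop("empty census for year(s): ", paste(yrs, collapse = ", "))
  }
  region <- unique(vapply(censuses, function(cn) cn$region_id, character(1)))
  thr <- unique(vapply(censuses, function(cn) as.numeric(cn$threshold), numeric(1)))
  if (length(region) != 1L || length(thr) != 1L) {
    stop("censuses must share one region and one threshold")
  }
  years <- vapply(censuses, function(cn) as.integer(cn$year), integer(1))
  ord <- order(years)
  years <- years[ord]
  s_max <- vapply(censuses, function(cn) cn$s_max, numeric(1))[ord]
  total <- vapply(censuses, function(cn) cn$total_forest, numeric(1))[ord]
  rs_max <- s_max / total
  structure(
    list(years = years, s_max = s_max, total_forest = total, rs_max = rs_max,
         delta_s_max = s_max - mean(s_max),
         delta_rs_max = rs_max - mean(rs_max),
         threshold = thr, region_id = region),
    class = "largest_patch_series"
  )
}

#' @export
print.largest_patch_series <- function(x, ...) {
  cat(sprintf("<largest_patch_series> %s @%g%%: %d years (%d-%d), mean RSmax %.3f\n",
              x$region_id, x$threshold, length(x$years), min(x$years),
              max(x$years), mean(x$rs_max)))
  invisible(x)
}

#' Sample skewness of the largest-patch fluctuations
#'
#' `g1 = m3 / m2^(3/2)` on `delta_rs_max` (identical to the skewness of
#' `rs_max` itself: skewness is shift-invariant). Negative skewness -
#' fluctuations below the average more frequent - is one of the
#' near-critical warning signs.
#'
#' @param x a `largest_patch_series` or a numeric vector.
#' @return the sample skewness (`NA` with a warning for zero variance).
#' @export
sample_skewness <- function(x) {
  v <- if (inherits(x, "largest_patch_series")) x$delta_rs_max else as.numeric(x)
  if (length(v) < 3L) stop("need at least 3 values")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) {
    warning("zero variance: skewness undefined")
    return(NA_real_)
  }
  mean((v - m)^3) / m2^1.5
}

#' Fit fluctuation-magnitude distributions
#'
#' Fits power-law, log-normal and exponential models to the absolute
#' fluctuation magnitudes `|delta|` (relative fluctuations by default) and
#' runs the model comparison. When no likelihood-ratio test against the
#' power law is significant at `alpha_level`, the best model is reported as
#' `"undetermined"` - with short series (e.g. 16 years) this is the typical
#' outcome.
#'
#' @param series a `largest_patch_series` or a numeric fluctuation vector.
#' @param relative use `delta_rs_max` (default) rather than `delta_s_max`.
#' @param alpha_level significance level for the LRTs.
#' @param min_tail minimum tail size for the x_min scan.
#' @return a `fluctuation_fit`: the `model_selection`, the reported
#'   `best_model` (possibly `"undetermined"`), and the tail class
#'   (`heavy`, `exponential`, `undetermined`).
#' @export
fit_fluctuations <- function(series, relative = TRUE, alpha_level = 0.05,
                             min_tail = 8L) {
  v <- if (inherits(series, "largest_patch_series")) {
    if (relative) series$delta_rs_max else series$delta_s_max
  } else {
    as.numeric(series)
  }
  if (length(v) < 8L) stop("need at least 8 fluctuation values")
  mag <- abs(v)
  mag <- mag[mag > 0]
  if (!length(mag) || sd(mag) == 0) stop("degenerate fluctuations: all equal")
  # rescale to data units (smallest magnitude = 1): the three families are
  # closed under scaling, and the lognormal's mu >= 0 constraint is meant
  # for sizes measured in units >= 1, not for relative magnitudes ~ 1e-2
  scale <- min(mag)
  mag <- mag / scale
  est <- estimate_xmin(mag, min_tail = min(min_tail, length(mag)))
  fits <- list(powerlaw = est$fit,
               lognormal = tryCatch(fit_lognormal(mag, est$x_min),
                                    error = function(e) structure(
                                      list(model = "lognormal", converged = FALSE),
                                      class = "fit_result")),
               exponential = fit_exponential(mag, est$x_min))
  sel <- select_model(fits)
  any_sig <- !is.null(sel$lrt) && any(sel$lrt$p_value < alpha_level)
  best <- if (any_sig) sel$best_model else "undetermined"
  tail_class <- if (!any_sig) "undetermined"
    else if (sel$best_model %in% c("powerlaw", "lognormal")) "heavy"
    else "exponential"
  structure(
    list(selection = sel, best_model = best, tail_class = tail_class,
         x_min = est$x_min * scale, scale = scale, n = length(mag)),
    class = "fluctuation_fit"
  )
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf("<fluctuation_fit> best: %s (tail: %s), x_min = %.4g, n = %d\n",
              x$best_model, x$tail_class, x$x_min, x$n))
  invisible(x)
}

# exact pinball-loss linear quantile fit used as slow-path/oracle;
# quantreg::rq is the production fitter
pinball_loss <- function(res, tau) sum(res * (tau - (res < 0)))

#' Variance trend of the fluctuation series by quantile regression
#'
#' Regresses the fluctuations on year at the upper and lower quantiles
#' (default 0.90 / 0.10). If the spread of the fluctuations grows, the upper
#' slope turns positive and/or the lower slope negative. Slope significance
#' is assessed by a seeded moving-block bootstrap of the residuals (block
#' length 4 by default, suited to short annual series with modest
#' autocorrelation). Direction is `increase` when the upper slope is
#' significantly positive or the lower significantly negative, `decrease`
#' for the reverse, `NS` otherwise; conflicting significant signals are
#' classified by the larger absolute slope and flagged.
#'
#' @param series a `largest_patch_series` or numeric vector (paired with
#'   `years` when a bare vector).
#' @param quantiles the two quantiles to track.
#' @param relative use `delta_rs_max` (default) or `delta_s_max`.
#' @param years time axis when `series` is a bare vector.
#' @param block_length moving-block bootstrap block length.
#' @param reps bootstrap replications.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level for the slope intervals.
#' @return a `trend_result`: per-quantile slope, its no-spread-trend null
#'   band and significance, plus the overall `direction` and a `conflict`
#'   flag.
#' @export
variance_trend <- function(series, quantiles = c(0.10, 0.90), relative = TRUE,
                           years = NULL, block_length = 4L, reps = 1000L,
                           seed = NULL, level = 0.95) {
  if (inherits(series, "largest_patch_series")) {
    y <- if (relative) series$delta_rs_max else series$delta_s_max
    t <- series$years
  } else {
    y <- as.numeric(series)
    t <- if (is.null(years)) seq_along(y) else years
  }
  n <- length(y)
  if (n < 8L) stop("need at least 8 time points")
  if (n < 2L * length(quantiles)) stop("too few points per quantile")
  if (!is.null(seed)) set.seed(seed)

  fit_one <- function(tau, tt, yy) {
    fit <- suppressWarnings(quantreg::rq(yy ~ tt, tau = tau))
    unname(coef(fit)[2])
  }
  slopes <- vapply(quantiles, fit_one, numeric(1), tt = t, yy = y)

  # Moving-block bootstrap of the residuals around each fitted quantile
  # line: blocks preserve short-range serial dependence, the refitted
  # slopes trace the sampling distribution of the quantile slope, and a
  # slope is significant when the percentile interval excludes zero.
  nb <- ceiling(n / block_length)
  starts_max <- n - block_length + 1L
  alpha2 <- (1 - level) / 2
  ci <- matrix(NA_real_, nrow = length(quantiles), ncol = 2)
  for (j in seq_along(quantiles)) {
    qfit <- suppressWarnings(quantreg::rq(y ~ t, tau = quantiles[j]))
    trendline <- stats::fitted(qfit)
    res <- y - trendline
    boot <- numeric(reps)
    for (r in seq_len(reps)) {
      st <- sample.int(starts_max, nb, replace = TRUE)
      idx <- as.vector(vapply(st, function(s) s:(s + block_length - 1L),
                              integer(block_length)))[1:n]
      boot[r] <- fit_one(quantiles[j], t, trendline + res[idx])
    }
    ci[j, ] <- quantile(boot, probs = c(alpha2, 1 - alpha2), names = FALSE,
                        na.rm = TRUE)
  }
  significant <- ci[, 1] > 0 | ci[, 2] < 0
  lo_i <- which.min(quantiles)
  hi_i <- which.max(quantiles)
  up_sig_pos <- significant[hi_i] && slopes[hi_i] > 0
  up_sig_neg <- significant[hi_i] && slopes[hi_i] < 0
  lo_sig_pos <- significant[lo_i] && slopes[lo_i] > 0
  lo_sig_neg <- significant[lo_i] && slopes[lo_i] < 0
  inc <- up_sig_pos || lo_sig_neg
  dec <- up_sig_neg || lo_sig_pos
  conflict <- inc && dec
  direction <- if (conflict) {
    # classify by the larger |slope| among the significant quantiles
    sig_idx <- which(significant)
    dom <- sig_idx[which.max(abs(slopes[sig_idx]))]
    widening <- (dom == hi_i && slopes[dom] > 0) || (dom == lo_i && slopes[dom] < 0)
    if (widening) "increase" else "decrease"
  } else if (inc) "increase" else if (dec) "decrease" else "NS"
  structure(
    list(quantiles = quantiles, slopes = slopes, ci = ci,
         significant = significant, direction = direction,
         conflict = conflict, block_length = block_length, reps = reps,
         seed = seed),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  for (j in seq_along(x$quantiles)) {
    cat(sprintf("  tau = %.2f: slope %.4g, null band [%.4g, %.4g]%s\n",
                x$quantiles[j], x$slopes[j], x$ci[j, 1], x$ci[j, 2],
                if (x$significant[j]) " *" else ""))
  }
  cat("  direction:", x$direction, if (x$conflict) "(conflicting signals)" else "", "\n")
  invisible(x)
}

#' Hartigan's dip statistic
#'
#' Maximum sup-norm distance between the empirical CDF and the closest
#' unimodal CDF (convex-concave construction with the mode free; an atom is
#' allowed at the mode). Lies in `[0, 0.25]`; equals `1/(2n)` for samples
#' whose ECDF is already compatible with a unimodal shape.
#'
#' @param x numeric sample (n >= 4 for [dip_test()]).
#' @return the dip statistic.
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 2L) stop("need at least 2 values")
  .dip_stat(x)
}

#' Dip test of unimodality with Monte-Carlo p-value
#'
#' Tests departure from unimodality of (typically) the pooled `rs_max`
#' values across regions and thresholds. The null reference is the uniform
#' distribution (the standard conservative choice): the p-value is the
#' fraction of `reps` uniform samples of the same size whose dip is at least
#' the observed one.
#'
#' @param x numeric sample, n >= 4.
#' @param reps Monte-Carlo replications (>= 2000 recommended).
#' @param seed integer seed.
#' @return a `dip_result` with `D`, `p_value`, `n`.
#' @export
dip_test <- function(x, reps = 2000L, seed = NULL) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 4L) stop("need at least 4 values for the dip test")
  if (!is.null(seed)) set.seed(seed)
  D <- .dip_stat(x)
  null_d <- .dip_null(n, as.integer(reps))
  p <- (sum(null_d >= D) + 1) / (reps + 1)
  structure(list(D = D, p_value = p, n = n, reps = reps),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("<dip_result> D = %.4f, p = %.4g (n = %d, %d Monte-Carlo reps)\n",
              x$D, x$p_value, x$n, x$reps))
  invisible(x)
}
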