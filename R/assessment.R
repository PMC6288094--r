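# Combine the per-threshold criteria into the near-critical fragmentation
# verdict and the fragmentation-state classification.

#' Classify the fragmentation state from RSmax at the 40% threshold
#'
#' Uses the most conservative cover threshold (40%): `rs_max > 0.6` is an
#' unfragmented (connected-phase) forest, `rs_max < 0.3` a fragmented one,
#' anything between is intermediate.
#'
#' @param rs_max_at_40 largest-patch proportion at the 40% threshold, in
#'   (0, 1\].
#' @return one of `"unfragmented"`, `"intermediate"`, `"fragmented"`.
#' @export
classify_state <- function(rs_max_at_40) {
  if (!is.finite(rs_max_at_40) || rs_max_at_40 <= 0 || rs_max_at_40 > 1) {
    stop("rs_max must lie in (0, 1]")
  }
  if (rs_max_at_40 > 0.6) "unfragmented"
  else if (rs_max_at_40 < 0.3) "fragmented"
  else "intermediate"
}

#' Per-threshold criterion set for one region
#'
#' Collects the boolean criteria per threshold. `fluctuation_tail` is
#' recorded for reporting but does not gate the verdict (short annual series
#' rarely discriminate the fluctuation-tail class).
#'
#' @param threshold percent thresholds (vector).
#' @param powerlaw_best was the power law the selected patch-size model at
#'   this threshold (logical, `NA` when fits failed)?
#' @param variance_increasing is the fluctuation variance increasing
#'   (quantile-regression direction `"increase"`)?
#' @param skewness_negative is the fluctuation skewness negative?
#' @param rs_max_at_40 scalar largest-patch proportion at 40%.
#' @param fluctuation_tail per-threshold tail class (`heavy`, `exponential`,
#'   `undetermined`).
#' @param region_id region label.
#' @return a `criterion_set` (data frame of criteria plus attributes).
#' @export
criterion_set <- function(threshold, powerlaw_best, variance_increasing,
                          skewness_negative, rs_max_at_40,
                          fluctuation_tail = "undetermined",
                          region_id = "region") {
  df <- data.frame(threshold = threshold,
                   powerlaw_best = powerlaw_best,
                   variance_increasing = variance_increasing,
                   skewness_negative = skewness_negative,
                   fluctuation_tail = fluctuation_tail,
                   stringsAsFactors = FALSE)
  structure(df, rs_max_at_40 = rs_max_at_40, region_id = region_id,
            class = c("criterion_set", "data.frame"))
}

#' Near-critical verdict for one region
#'
#' A region is flagged near the critical fragmentation point when, at one
#' and the same threshold, the patch-size distribution is best described by
#' a power law, the fluctuation variance is increasing, and the fluctuation
#' skewness is negative. All three must hold simultaneously for at least one
#' threshold. The fragmentation state comes from [classify_state()] on
#' `rs_max_at_40`.
#'
#' @param criteria a [criterion_set()].
#' @return a `criticality_verdict` with `near_critical`,
#'   `qualifying_thresholds`, `state`, `indeterminate` flag.
#' @export
assess_region <- function(criteria) {
  stopifnot(inherits(criteria, "criterion_set"))
  if (nrow(criteria) < 1L) stop("criteria must cover at least one threshold")
  complete <- stats::complete.cases(
    criteria[, c("powerlaw_best", "variance_increasing", "skewness_negative")])
  if (!any(complete)) {
    return(structure(
      list(region_id = attr(criteria, "region_id"), near_critical = NA,
           qualifying_thresholds = numeric(0),
           state = tryCatch(classify_state(attr(criteria, "rs_max_at_40")),
                            error = function(e) NA_character_),
           indeterminate = TRUE),
      class = "criticality_verdict"))
  }
  hit <- complete & criteria$powerlaw_best & criteria$variance_increasing &
    criteria$skewness_negative
  structure(
    list(region_id = attr(criteria, "region_id"),
         near_critical = any(hit),
         qualifying_thresholds = criteria$threshold[hit],
         state = classify_state(attr(criteria, "rs_max_at_40")),
         indeterminate = FALSE),
    class = "criticality_verdict"
  )
}

#' @export
print.criticality_verdict <- function(x, ...) {
  cat(sprintf("<criticality_verdict> %s: %s, state %s%s\n",
              x$region_id,
              if (isTRUE(x$near_critical)) {
                paste0("NEAR CRITICAL (thresholds ",
                       paste(x$qualifying_thresholds, collapse = ", "), ")")
              } else if (isTRUE(x$indeterminate)) "indeterminate"
              else "not near critical",
              x$state,
              if (isTRUE(x$indeterminate)) " [incomplete criteria]" else ""))
  invisible(x)
}

#' Compute the criterion set for one region from yearly censuses
#'
#' Runs the full per-threshold analysis: per-year four-model patch-size
#' fits (power law declared best at a threshold when it is the selected
#' model in more than half of the years), fluctuation variance trend by
#' quantile regression, fluctuation skewness, and the fluctuation-tail
#' class.
#'
#' @param censuses_by_threshold named list (one element per threshold) of
#'   yearly `patch_census` lists.
#' @param seed integer seed for the trend bootstrap.
#' @param min_tail,max_candidates tail-fit controls (see [estimate_xmin()]).
#' @param trend_reps bootstrap replications for [variance_trend()].
#' @return a list with the [criterion_set()], per-threshold detail
#'   (`series`, `trend`, `skewness`, `yearly_best`), and `rs_max_at_40`.
#' @export
region_criteria <- function(censuses_by_threshold, seed = 1L,
                            min_tail = 10L, max_candidates = 400L,
                            trend_reps = 1000L) {
  thr <- vapply(censuses_by_threshold,
                function(cl) as.numeric(cl[[1]]$threshold), numeric(1))
  region <- censuses_by_threshold[[1]][[1]]$region_id
  detail <- vector("list", length(thr))
  pl_best <- var_inc <- skew_neg <- rep(NA, length(thr))
  tail_class <- rep("undetermined", length(thr))
  skews <- rep(NA_real_, length(thr))
  for (i in seq_along(thr)) {
    cl <- censuses_by_threshold[[i]]
    yearly_best <- vapply(cl, function(cn) {
      tryCatch(fit_patch_models(cn$sizes, min_tail = min_tail,
                                max_candidates = max_candidates)$selection$best_model,
               error = function(e) NA_character_)
    }, character(1))
    pl_best[i] <- mean(yearly_best == "powerlaw", na.rm = TRUE) > 0.5
    series <- build_series(cl)
    trend <- variance_trend(series, seed = seed + i, reps = trend_reps)
    var_inc[i] <- trend$direction == "increase"
    skews[i] <- sample_skewness(series)
    skew_neg[i] <- is.finite(skews[i]) && skews[i] < 0
    fl <- tryCatch(fit_fluctuations(series), error = function(e) NULL)
    if (!is.null(fl)) tail_class[i] <- fl$tail_class
    detail[[i]] <- list(series = series, trend = trend,
                        skewness = skews[i], yearly_best = yearly_best,
                        fluctuations = fl)
  }
  # RSmax at the most conservative threshold present (40% when available)
  i40 <- which.max(thr)
  rs40 <- mean(detail[[i40]]$series$rs_max)
  cs <- criterion_set(threshold = thr, powerlaw_best = pl_best,
                      variance_increasing = var_inc,
                      skewness_negative = skew_neg,
                      rs_max_at_40 = rs40,
                      fluctuation_tail = tail_class,
                      region_id = region)
  list(criteria = cs, detail = detail, rs_max_at_40 = rs40,
       skewness = skews)
}

#' Table-style verdict report for a set of regions
#'
#' @param results named list: per region, the output of [region_criteria()].
#' @return data frame with one row per region x threshold: RSmax at 40%,
#'   variance direction, skewness, power-law flag, tail class, state and the
#'   combined verdict.
#' @export
verdict_table <- function(results) {
  rows <- lapply(names(results), function(rid) {
    res <- results[[rid]]
    v <- assess_region(res$criteria)
    data.frame(region = rid,
               threshold = res$criteria$threshold,
               rs_max_40 = round(res$rs_max_at_40, 4),
               powerlaw_best = res$criteria$powerlaw_best,
               variance = vapply(res$detail, function(d) d$trend$direction,
                                 character(1)),
               skewness = round(res$skewness, 4),
               fluctuation_tail = res$criteria$fluctuation_tail,
               state = v$state,
               near_critical = v$near_critical,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
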