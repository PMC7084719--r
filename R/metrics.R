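#' Unsafe-behavior ratio
#'
#' Unsafe worker-day acts divided by all worker-day acts, pooled over the
#' records in scope. Foremen's own acts are excluded unless
#' `include_foremen`.
#'
#' @param records a trace data.frame from [run_simulation()].
#' @param include_foremen include foreman rows.
#' @return Proportion in `[0, 1]`.
#' @export
unsafe_behavior_ratio <- function(records, include_foremen = FALSE) {
  if (is.null(records) || nrow(records) == 0) stop("no records")
  if (!include_foremen) records <- records[records$is_foreman == 0, ]
  mean(records$UB)
}

#' Accident statistics
#'
#' Accident rate expressed as accidents per 100 full-time workers per
#' day, `100 * accidents / (n_workers * n_days)`, plus the ratio of
#' near-miss to accident counts. The per-run-total alternative
#' (`100 * accidents / n_workers`, ignoring the day dimension) is also
#' returned.
#'
#' @param records a trace data.frame.
#' @param include_foremen include foreman rows.
#' @return List with `accident_rate`, `accident_rate_run_total`,
#'   `near_miss_to_accident` (`Inf` when near misses occur without any
#'   accident, `NA` when neither occurs), and raw counts.
#' @export
accident_stats <- function(records, include_foremen = FALSE) {
  if (is.null(records) || nrow(records) == 0) stop("no records")
  if (!include_foremen) records <- records[records$is_foreman == 0, ]
  n_acc <- sum(records$accident)
  n_nm <- sum(records$near_miss)
  n_workers <- length(unique(records$id))
  n_days <- length(unique(records$day))
  list(
    accidents = n_acc,
    near_misses = n_nm,
    accident_rate = 100 * n_acc / nrow(records),
    accident_rate_run_total = 100 * n_acc / n_workers,
    near_miss_to_accident = if (n_acc > 0) n_nm / n_acc
                            else if (n_nm > 0) Inf else NA_real_,
    n_workers = n_workers, n_days = n_days
  )
}

#' Ordinary least squares fit
#'
#' Thin wrapper around [stats::lm()] for the validation regressions
#' (e.g. risk acceptance on attitude over pooled worker-day pairs).
#'
#' @param x predictor series.
#' @param y response series.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Pearson correlation
#'
#' Wrapper around [stats::cor()] with the degenerate-variance guard used
#' by the validation diagnostics.
#'
#' @param x,y numeric series of equal length >= 3.
#' @return Sample Pearson correlation.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate variance")
  stats::cor(x, y)
}

#' Classify cognitive failures
#'
#' Labels each worker-day by which stage of the cognitive process failed:
#' * `stage1_not_found`: the hazard was never registered (`PR = 0`) and
#'   the act was unsafe;
#' * `stage2_underestimated`: the hazard was registered but understood
#'   below its perceived level (`UR < PR`) and the act was unsafe;
#' * `stage3_acceptance`: the hazard was understood at or above its
#'   perceived level, yet accepted (`UB = 1`);
#' * `corrected`: understanding fell below perception, but the social
#'   norms still pulled acceptance low enough for a safe act;
#' * `none`: safe behavior with no cognitive bias.
#'
#' The classification is exhaustive and mutually exclusive.
#'
#' @param records a trace data.frame (or any data.frame with `PR`, `UR`,
#'   `UB` columns).
#' @return Factor of case labels, one per row.
#' @export
classify_failure <- function(records) {
  pr <- records$PR; ur <- records$UR; ub <- records$UB
  lab <- ifelse(ub == 1,
                ifelse(pr == 0, "stage1_not_found",
                       ifelse(ur < pr, "stage2_underestimated",
                              "stage3_acceptance")),
                ifelse(pr > 0 & ur < pr, "corrected", "none"))
  factor(lab, levels = c("stage1_not_found", "stage2_underestimated",
                         "stage3_acceptance", "corrected", "none"))
}

#' Extract example failure cases from a trace
#'
#' Picks one representative worker-day per failure class, with the state
#' snapshot columns used when discussing why each stage failed.
#'
#' @param records a trace data.frame.
#' @return data.frame with one row per class present in the trace.
#' @export
failure_cases <- function(records) {
  records <- records[records$is_foreman == 0, ]
  cls <- classify_failure(records)
  keep <- c("day", "id", "AR", "PR", "UR", "RA", "UB", "AT",
            "WN", "FN", "MN", "CN3", "CN2", "KL", "SA")
  out <- do.call(rbind, lapply(levels(cls), function(lv) {
    i <- which(cls == lv)
    if (length(i) == 0) return(NULL)
    r <- records[i[1], keep]
    r$case <- lv
    r
  }))
  names(out)[names(out) == "CN3"] <- "ST"
  names(out)[names(out) == "CN2"] <- "FCN"
  rownames(out) <- NULL
  out
}

#' Validation statistics of a baseline run
#'
#' The model's replicative-validity diagnostics: the pooled
#' unsafe-behavior ratio, accident rate and near-miss:accident ratio; the
#' OLS fit of risk acceptance on attitude over pooled worker-day pairs;
#' and worker-day Pearson correlations of safety awareness with the
#' foreman-communication and training channels. All are computed from the
#' run's pooled sufficient statistics, so they are available even when
#' the trace was dropped.
#'
#' @param run an `sc_run`.
#' @return Named list (a subset of [run_summary()]).
#' @export
validation_stats <- function(run) {
  s <- run_summary(run)
  s[c("unsafe_ratio", "accident_rate", "near_miss_to_accident",
      "attitude_ra_slope", "attitude_ra_intercept", "attitude_ra_r_squared",
      "r_comm_awareness", "r_training_awareness",
      "first_day_unsafe", "final_day_unsafe")]
}

#' Comparison against packaged empirical anchors
#'
#' Compares a replicate batch against the packaged empirical anchors
#' (roughly one third of acts unsafe; the classical near-miss:accident
#' proportion of about 10:1; a recordable-injury rate of 3.2 per 100
#' full-time workers). The anchors are comparison fixtures, not inputs to
#' the simulation.
#'
#' @param reps an `sc_replicates`.
#' @return data.frame with simulated means and anchor values.
#' @export
validation_report <- function(reps) {
  anchors <- jsonlite::read_json(
    system.file("extdata", "empirical_anchors.json", package = "sociocog",
                mustWork = TRUE), simplifyVector = TRUE)
  tab <- replicate_summary(reps)
  pooled_nm <- sum(tab$near_misses) / sum(tab$accidents)
  data.frame(
    item = c("unsafe_behavior_ratio", "near_miss_to_accident",
             "accident_rate"),
    simulated = c(mean(tab$unsafe_ratio), pooled_nm,
                  mean(tab$accident_rate)),
    empirical = c(anchors$unsafe_behavior_ratio,
                  anchors$near_miss_to_accident,
                  anchors$accident_rate),
    source = c(anchors$unsafe_behavior_ratio_source,
               anchors$near_miss_to_accident_source,
               anchors$accident_rate_source)
  )
}
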