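make_records <- function(ub, accident = 0 * ub, near_miss = ub - accident,
                         is_foreman = 0 * ub) {
  n <- length(ub)
  data.frame(day = rep(1, n), id = seq_len(n), is_foreman = is_foreman,
             UB = ub, accident = accident, near_miss = near_miss,
             PR = runif(n), UR = runif(n), RA = runif(n))
}

test_that("unsafe-behavior ratio is the pooled unsafe share", {
  r <- make_records(c(rep(1, 3), rep(0, 7)))
  expect_equal(unsafe_behavior_ratio(r), 0.3)
  expect_equal(unsafe_behavior_ratio(make_records(rep(0, 5))), 0)
  expect_error(unsafe_behavior_ratio(r[0, ]), "no records")
  # mediant property: a pooled ratio lies between its subset ratios
  r1 <- make_records(c(1, 1, 0, 0)); r2 <- make_records(rep(c(1, 0), 5))
  pooled <- unsafe_behavior_ratio(rbind(r1, r2))
  expect_gte(pooled, min(0.5, 0.5)); expect_lte(pooled, max(0.5, 0.5))
  r3 <- make_records(c(1, 0, 0, 0))
  pooled <- unsafe_behavior_ratio(rbind(r1, r3))
  expect_true(pooled >= 0.25 && pooled <= 0.5)
})

test_that("accident statistics follow the per-100-workers-per-day reading", {
  ub <- rep(1, 100)
  r <- make_records(ub, accident = c(rep(1, 10), rep(0, 90)))
  s <- accident_stats(r)
  expect_equal(s$near_miss_to_accident, 9.0)
  expect_equal(s$accident_rate, 100 * 10 / 100)
  none <- accident_stats(make_records(rep(0, 10)))
  expect_true(is.na(none$near_miss_to_accident))
  nm_only <- accident_stats(make_records(rep(1, 10)))
  expect_identical(nm_only$near_miss_to_accident, Inf)
})

test_that("ols and pearson agree with closed forms", {
  withr::with_seed(21, {
    x <- runif(200); y <- 2 * x
    f <- suppressWarnings(ols_fit(x, y))  # lm flags the perfect fit
    expect_equal(f$slope, 2, tolerance = 1e-10)
    expect_equal(f$intercept, 0, tolerance = 1e-10)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
    y <- 0.3 + 1.7 * x + rnorm(200, sd = 0.2)
    f <- ols_fit(x, y)
    # independent closed-form implementation
    slope <- cov(x, y) / var(x)
    expect_equal(f$slope, slope, tolerance = 1e-10)
    expect_equal(f$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
    expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-10)
    r <- pearson(x, y)
    expect_equal(r, sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
                 tolerance = 1e-10)
    expect_equal(pearson(x, x), 1)
    expect_equal(pearson(x, -x), -1)
    expect_error(ols_fit(rep(1, 10), runif(10)), "zero variance")
    expect_error(pearson(x[1:2], y[1:2]), "length")
  })
})

test_that("cognitive-failure classification matches the printed case rows", {
  cases <- data.frame(
    PR = c(0, 0.522, 0.453, 0.595),
    UR = c(0, 0.343, 0.573, 0.478),
    UB = c(1, 1, 1, 0))
  expect_equal(as.character(classify_failure(cases)),
               c("stage1_not_found", "stage2_underestimated",
                 "stage3_acceptance", "corrected"))
  safe <- data.frame(PR = 0.4, UR = 0.5, UB = 0)
  expect_equal(as.character(classify_failure(safe)), "none")
})

test_that("classification is exhaustive and mutually exclusive", {
  run <- run_simulation(site_config(n_days = 30), seed = 13)
  cls <- classify_failure(run$records)
  expect_false(anyNA(cls))
  expect_equal(length(cls), nrow(run$records))
  # the stage taxonomy partitions unsafe acts; safe acts are corrected/none
  unsafe <- run$records$UB == 1
  expect_true(all(cls[unsafe] %in% c("stage1_not_found",
                                     "stage2_underestimated",
                                     "stage3_acceptance")))
  expect_true(all(cls[!unsafe] %in% c("corrected", "none")))
  ex <- failure_cases(run$records)
  expect_true(all(c("ST", "FCN", "case") %in% names(ex)))
})

test_that("run summary statistics agree with trace-level recomputation", {
  run <- run_simulation(site_config(n_days = 40), seed = 17)
  w <- run$records[run$records$is_foreman == 0, ]
  expect_equal(run$summary$unsafe_ratio, mean(w$UB), tolerance = 1e-12)
  s <- accident_stats(run$records)
  expect_equal(run$summary$accident_rate, s$accident_rate, tolerance = 1e-12)
  f <- ols_fit(w$AT, w$RA)
  expect_equal(run$summary$attitude_ra_slope, f$slope, tolerance = 1e-10)
  expect_equal(run$summary$attitude_ra_r_squared, f$r_squared,
               tolerance = 1e-10)
  expect_equal(run$summary$r_comm_awareness, pearson(w$CN2, w$SA),
               tolerance = 1e-10)
  expect_equal(run$summary$r_training_awareness, pearson(w$CN3, w$SA),
               tolerance = 1e-10)
  v <- validation_stats(run)
  expect_named(v, c("unsafe_ratio", "accident_rate", "near_miss_to_accident",
                    "attitude_ra_slope", "attitude_ra_intercept",
                    "attitude_ra_r_squared", "r_comm_awareness",
                    "r_training_awareness", "first_day_unsafe",
                    "final_day_unsafe"))
})

test_that("validation report compares against the packaged anchors", {
  reps <- run_replicates(site_config(n_days = 30), n_runs = 2, base_seed = 1)
  rep <- validation_report(reps)
  expect_equal(rep$item, c("unsafe_behavior_ratio", "near_miss_to_accident",
                           "accident_rate"))
  expect_equal(rep$empirical, c(0.3333, 10.0, 3.2))
  expect_true(all(is.finite(rep$simulated)))
})
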