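test_that("population initialization is sized and seeded correctly", {
  cfg <- site_config()
  s1 <- init_population(cfg, seed = 1)
  expect_equal(s1$n_w, 100L)
  expect_equal(s1$n_f, 5L)
  expect_true(all(s1$workers$at >= 0.4 & s1$workers$at <= 0.9))
  expect_true(all(s1$workers$p >= 0.6 & s1$workers$p <= 1.2))
  expect_true(all(s1$workers$wn >= 0.4 & s1$workers$wn <= 0.9))
  s2 <- init_population(cfg, seed = 1)
  expect_identical(s1, s2)
  s3 <- init_population(cfg, seed = 2)
  expect_false(identical(s1$workers$at, s3$workers$at))
})

test_that("identical (config, seed) pairs give identical runs", {
  cfg <- tiny_config(n_days = 20)
  r1 <- run_simulation(cfg, seed = 99)
  r2 <- run_simulation(cfg, seed = 99)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$daily, r2$daily)
  expect_identical(r1$summary, r2$summary)
  f1 <- tempfile(); f2 <- tempfile()
  write_trace(r1, f1); write_trace(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a scripted small site reproduces the straight-line oracle trace", {
  for (seed in c(1, 7, 123)) {
    cfg <- tiny_config()
    got <- run_simulation(cfg, seed = seed)$records
    want <- oracle_run(cfg, seed = seed)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # larger crew, more days, demonstration disabled
  cfg <- site_config(n_groups = 1, workers_per_group = 5, n_days = 6,
                     k_comm_pool = 2, demo_role_enabled = FALSE)
  expect_equal(run_simulation(cfg, seed = 5)$records,
               oracle_run(cfg, seed = 5), tolerance = 1e-12)
})

test_that("every unsafe act resolves into exactly one accident or near miss", {
  run <- run_simulation(site_config(n_days = 40), seed = 3)
  r <- run$records
  expect_true(all(r$UB == r$accident + r$near_miss))
  expect_true(all(r$accident %in% c(0, 1) & r$near_miss %in% c(0, 1)))
  # detection failure forces an unregistered hazard and an unsafe act
  expect_true(all(r$PR[r$FR == 0] == 0))
  expect_true(all(r$UR[r$PR == 0] == 0))
  expect_true(all(r$UB[r$UR == 0 & r$RA > 0] == 1))
})

test_that("limiting configurations behave as the equations dictate", {
  # a safe environment produces no accidents
  run <- run_simulation(site_config(n_days = 30, env_risk_er = 0), seed = 4)
  expect_equal(sum(run$records$accident), 0)
  expect_equal(sum(run$records$near_miss), sum(run$records$UB))
  # zero social identity decouples risk acceptance from the norms
  cfg <- site_config(n_days = 30, social_identity_w = 0,
                     epsilon = dist_spec("uniform", 0, 0))
  run <- run_simulation(cfg, seed = 5)
  expect_equal(run$records$RA, run$records$AT, tolerance = 1e-12)
  # zero training frequency means no meetings ever
  run <- run_simulation(site_config(n_days = 30, training_freq = 0), seed = 6)
  expect_equal(sum(run$records$CN3), 0)
})

test_that("degenerate horizon yields an empty trace with valid metadata", {
  run <- run_simulation(site_config(n_days = 0), seed = 1)
  expect_equal(nrow(run$daily), 0)
  expect_true(is.na(run$summary$unsafe_ratio))
  expect_equal(run$seed, 1)
})

test_that("replicates derive seeds as base_seed + k - 1", {
  cfg <- tiny_config(n_days = 10)
  reps <- run_replicates(cfg, n_runs = 3, base_seed = 42)
  expect_equal(vapply(reps, function(r) r$seed, 1), c(42, 43, 44))
  solo <- run_simulation(cfg, seed = 42, keep_records = FALSE)
  expect_identical(reps[[1]]$summary, solo$summary)
  tab <- replicate_summary(reps)
  expect_equal(nrow(tab), 3)
})

test_that("meeting frequency is honored over the horizon", {
  run <- run_simulation(site_config(n_days = 280, n_groups = 1,
                                    workers_per_group = 2, k_comm_pool = 1),
                        seed = 8)
  meetings <- sum(run$daily$training)
  expect_lt(abs(meetings - 140), 3 * sqrt(280 * 0.25))
})

test_that("feedback flags occur at the configured conditional frequencies", {
  cfg <- site_config(n_days = 120)
  run <- run_simulation(cfg, seed = 9)
  r <- run$records[run$records$is_foreman == 0, ]
  r <- r[order(r$id, r$day), ]
  prev_ub <- ave(r$UB, r$id, FUN = function(x) c(NA, x[-length(x)]))
  after_unsafe <- !is.na(prev_ub) & prev_ub == 1
  after_safe <- !is.na(prev_ub) & prev_ub == 0
  neg_rate <- mean(r$MF[after_unsafe])
  pos_rate <- mean(r$PMF[after_safe])
  expect_equal(neg_rate, 0.6, tolerance = 0.05)
  expect_equal(pos_rate, 0.1, tolerance = 0.05)
  # negative feedback never follows a safe act, positive never an unsafe one
  expect_equal(sum(r$MF[after_safe]), 0)
  expect_equal(sum(r$PMF[after_unsafe]), 0)
})
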