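test_that("awareness and knowledge recompute from baseline plus event gains", {
  ci_a <- c(0.01, 0.2, 0.2); ci_k <- c(0.01, 0.2, 0.1)
  expect_equal(update_awareness(0.8, c(0, 0, 0), ci_a), 0.8)
  expect_equal(update_awareness(0.8, c(0, 1, 0), ci_a), 1.0)
  expect_equal(update_awareness(0.8, c(0, 1, 1), ci_a), 1.2)
  expect_equal(update_knowledge(0.8, c(0, 0, 1), ci_k), 0.9)
  expect_equal(update_knowledge(0.8, c(0, 1, 1), ci_k), 1.1)
  # matrix form, one row per agent
  cn <- rbind(c(2, 1, 0), c(0, 0, 1))
  expect_equal(update_awareness(0.8, cn, ci_a), c(0.8 + 0.22, 1.0))
  expect_error(update_awareness(0.8, c(-1, 0, 0), ci_a), "nonnegative")
})

test_that("demonstration perceptions straddle the actual risk", {
  expect_true(all(perceive_demonstration(0.44, 1, runif(100)) > 0.44))
  expect_true(all(perceive_demonstration(0.44, 0, runif(100)) < 0.44))
  withr::with_seed(3, {
    # uniform-mean oracle: observing an unsafe act at AR = 0.5 averages 0.75
    mu <- mean(perceive_demonstration(0.5, 1, runif(1e5)))
    expect_equal(mu, 0.75, tolerance = 0.005)
    # property over random cases: perception > AR iff the act was unsafe
    for (i in 1:100) {
      ar <- runif(1); ub <- rbinom(1, 1, 0.5)
      v <- perceive_demonstration(ar, ub, runif(1))
      expect_true(if (ub == 1) v >= ar else v <= ar)
    }
  })
})

test_that("feedback perception follows the four-branch rule", {
  expect_equal(perceive_feedback(0.3, 0, 0.5, 0, 0, 0.9), 0.3)  # carry
  v <- perceive_feedback(0.3, 0, 0.5, 1, 0, 0.7)
  expect_true(v > 0 && v < 0.5)
  v <- perceive_feedback(0.3, 1, 0.5, 0, 1, 0.7)
  expect_true(v > 0 && v < 0.5)
  v <- perceive_feedback(0.3, 1, 0.5, 0, 0, 0.7)  # tacit approval
  expect_true(v > 0.5 && v < 1)
})

test_that("norm updates are convex and [0,1]-preserving", {
  expect_equal(update_foreman_norm(0.4, 0.6, 0.2, 1.0, 0.5, TRUE), 0.4)
  expect_equal(update_foreman_norm(0.4, 0.9, 0.1, 0.0, 0.5, TRUE), 0.4)
  expect_equal(update_foreman_norm(0.4, 0.6, 0.2, 0.5, 0.5, FALSE), 0.3)
  expect_equal(update_coworker_norm(0.4, 0.6, 0.5), 0.5)
  expect_equal(update_coworker_norm(0.4, c(0.2, 0.6), 1.0), 0.4)
  expect_equal(update_coworker_norm(0.4, c(0.2, 0.6), 0.0), 0.4)
  expect_equal(update_coworker_norm(0.4, numeric(0), 0.3), 0.4)  # no observations
  expect_equal(update_manager_norm(0.2, 0.4, 0.5), 0.3)
  expect_equal(update_manager_norm(0.2, 0.4, 0.0), 0.2)
  expect_equal(update_manager_norm(0.2, 0.4, 1.0), 0.4)
  withr::with_seed(5, {
    for (i in 1:200) {
      prev <- runif(1); m <- runif(1); d <- runif(1)
      sig1 <- runif(1); sig2 <- runif(1)
      fn <- update_foreman_norm(prev, sig1, sig2, m, d, TRUE)
      expect_gte(fn, min(prev, sig1, sig2) - 1e-12)
      expect_lte(fn, max(prev, sig1, sig2) + 1e-12)
      pra <- runif(sample(1:5, 1))
      wn <- update_coworker_norm(prev, pra, m)
      expect_gte(wn, min(prev, pra) - 1e-12)
      expect_lte(wn, max(prev, pra) + 1e-12)
      mn <- update_manager_norm(prev, sig1, m)
      expect_true(mn >= 0 && mn <= 1)
    }
  })
})

test_that("norms converge geometrically to a constant perception signal", {
  for (s in c(0.1, 0.9)) {
    fn <- 0.5; mn <- 0.5; wn <- 0.5
    for (t in 1:200) {
      fn <- update_foreman_norm(fn, s, s, 0.3, 0.5, TRUE)
      mn <- update_manager_norm(mn, s, 0.3)
      wn <- update_coworker_norm(wn, s, 0.3)
    }
    expect_equal(fn, s, tolerance = 1e-8)
    expect_equal(mn, s, tolerance = 1e-8)
    expect_equal(wn, s, tolerance = 1e-8)
  }
})

test_that("risk acceptance blends attitude and weighted norms", {
  w3 <- c(coworker = 0.2, foreman = 0.45, manager = 0.35)
  # printed worked case: core gives 0.399, residual 0.004 reproduces 0.403
  core <- compute_risk_acceptance(0.578, 0.305, 0.237, 0.150, 0.5, w3, eps = 0)
  expect_equal(core, 0.399, tolerance = 5e-4)
  expect_equal(compute_risk_acceptance(0.578, 0.305, 0.237, 0.150, 0.5, w3,
                                       eps = 0.004), 0.403, tolerance = 5e-4)
  expect_equal(compute_risk_acceptance(0.7, 0.1, 0.2, 0.3, 0, w3, 0), 0.7)
  expect_equal(compute_risk_acceptance(0.9, 0.5, 0.5, 0.5, 1, w3, 0), 0.5)
  expect_error(compute_risk_acceptance(0.5, 0.5, 0.5, 0.5, 0.5,
                                       c(coworker = 0.5, foreman = 0.5,
                                         manager = 0.5), 0),
               "sum to 1")
  # individual (legacy) mode
  expect_equal(compute_risk_acceptance_individual(0.6, 0.4, 0.5, 0.5), 0.5)
  expect_equal(compute_risk_acceptance_individual(0.6, 0.6, 0.5, 0.5), 0.6)
  expect_equal(compute_risk_acceptance_individual(0.3, 0.3, 0.7, 0.3), 0.3)
  expect_equal(subjective_norm(0.2, 0.4, 0.6, w3), 0.2 * 0.2 + 0.45 * 0.4 +
                 0.35 * 0.6)
})

test_that("excluded norms have exactly zero influence on risk acceptance", {
  cfg <- site_config()
  for (nm in c("coworker", "foreman", "manager")) {
    v <- exclude_norm(cfg, nm)
    vals <- c(coworker = 0.3, foreman = 0.6, manager = 0.9)
    ra1 <- compute_risk_acceptance(0.5, vals[["coworker"]], vals[["foreman"]],
                                   vals[["manager"]], 0.5, v$norm_weights, 0)
    vals[nm] <- 0.01
    ra2 <- compute_risk_acceptance(0.5, vals[["coworker"]], vals[["foreman"]],
                                   vals[["manager"]], 0.5, v$norm_weights, 0)
    expect_identical(ra1, ra2)
  }
})
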