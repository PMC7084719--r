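#' Initialize the site population
#'
#' Builds the site state: `n_groups` crews, each with one foreman and
#' `workers_per_group` workers. Worker and foreman attitudes and
#' risk-understanding coefficients are drawn from the configured initial
#' distributions; awareness and knowledge start at their baselines;
#' initial norm perceptions are drawn from the same interval as initial
#' attitudes. Foremen run the full cognitive loop themselves, but their
#' risk acceptance carries no foreman-norm term (nobody supervises them
#' within the crew); its weight is dropped and the remaining norm weights
#' renormalized.
#'
#' Initialization consumes random draws in a fixed, documented order
#' (worker attitudes, worker coefficients, worker coworker/foreman/manager
#' norms, then the same blocks for foremen with coworker and manager norms
#' only), which together with the [step_day()] draw order forms the
#' package's reproducibility contract: the same `(config, seed)` always
#' yields bit-identical runs.
#'
#' @param cfg an `sc_config`.
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is
#'   called first.
#' @return A site state list of class `sc_state`.
#' @export
init_population <- function(cfg, seed = NULL) {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n_f <- cfg$n_groups
  n_w <- cfg$n_groups * cfg$workers_per_group
  wpg <- cfg$workers_per_group
  group_w <- rep(seq_len(n_f), each = wpg)

  w <- list(
    group = group_w,
    at  = r_dist(n_w, cfg$attitude_init),
    p   = r_dist(n_w, cfg$coeff_init),
    wn  = r_dist(n_w, cfg$attitude_init),
    fn  = r_dist(n_w, cfg$attitude_init),
    mn  = r_dist(n_w, cfg$attitude_init)
  )
  w$at_lag <- w$at
  w$kl_lag <- rep(cfg$kl0, n_w)
  w$sa_prev <- rep(cfg$sa0, n_w)
  w$kl_prev <- rep(cfg$kl0, n_w)
  w$pr_sum <- numeric(n_w)
  w$pr_nzsum <- numeric(n_w)
  w$pr_nzcnt <- integer(n_w)
  w$ub_prev <- integer(n_w)
  w$ur_prev <- numeric(n_w)
  w$ar_prev <- numeric(n_w)

  f <- list(
    group = seq_len(n_f),
    at  = r_dist(n_f, cfg$attitude_init),
    p   = r_dist(n_f, cfg$coeff_init),
    wn  = r_dist(n_f, cfg$attitude_init),
    mn  = r_dist(n_f, cfg$attitude_init)
  )
  f$at_lag <- f$at
  f$kl_lag <- rep(cfg$kl0, n_f)
  f$sa_prev <- rep(cfg$sa0, n_f)
  f$kl_prev <- rep(cfg$kl0, n_f)
  f$pr_sum <- numeric(n_f)
  f$pr_nzsum <- numeric(n_f)
  f$pr_nzcnt <- integer(n_f)
  f$ub_prev <- integer(n_f)
  f$ur_prev <- numeric(n_f)
  f$ar_prev <- numeric(n_f)
  f$ub_today <- integer(n_f)
  f$ar_today <- numeric(n_f)

  # observation pools: workers observe fellow workers of their crew
  # (never the foreman; he enters through the foreman norm), foremen
  # observe all workers of their crew. With k_observed set, the first
  # k_observed crew-mates in index order are observed.
  k_obs <- if (is.null(cfg$k_observed)) wpg - 1L else cfg$k_observed
  obs_w <- if (k_obs > 0) {
    t(vapply(seq_len(n_w), function(i) {
      mates <- which(group_w == group_w[i])
      mates <- mates[mates != i]
      mates[seq_len(k_obs)]
    }, integer(k_obs)))
  } else {
    matrix(integer(0), nrow = n_w, ncol = 0)
  }
  obs_f <- t(vapply(seq_len(n_f), function(g) which(group_w == g),
                    integer(wpg)))

  # foreman risk-acceptance weights: drop the foreman component,
  # renormalize what remains (degenerate all-zero case: attitude only)
  wts <- cfg$norm_weights
  fw <- c(coworker = unname(wts[["coworker"]]), foreman = 0,
          manager = unname(wts[["manager"]]))
  f_w_eff <- cfg$social_identity_w
  if (sum(fw) > 0) fw <- fw / sum(fw) else f_w_eff <- 0

  structure(list(
    day = 0L,
    n_w = n_w, n_f = n_f, wpg = wpg, k_obs = k_obs,
    workers = w, foremen = f,
    obs_w = obs_w, obs_f = obs_f,
    foreman_weights = fw, foreman_w = f_w_eff
  ), class = "sc_state")
}

# one fixed-length block of interaction draws for the day; see step_day
# for where each block sits in the stream
draw_interactions <- function(state, cfg) {
  n_w <- state$n_w
  st <- as.integer(stats::runif(1) < cfg$training_freq)
  cn1 <- stats::rbinom(n_w, cfg$k_comm_pool, cfg$comm_freq_coworker)
  cn2 <- as.integer(stats::runif(n_w) < cfg$comm_freq_foreman)
  # foremen receive safety communication from site management at the
  # same per-day frequency (they have no foreman of their own and no
  # coworker conversation pool)
  cn2_f <- as.integer(stats::runif(state$n_f) < cfg$comm_freq_foreman)
  list(st = st, cn1 = cn1, cn2 = cn2, cn2_f = cn2_f)
}

# feedback occurrence flags conditioned on the previous day's behavior:
# positive feedback can only follow a safe act, negative an unsafe one.
# One uniform per agent decides whichever branch applies.
draw_feedback_flags <- function(ub_prev, pos_freq, neg_freq, u) {
  pos <- as.integer(ub_prev == 0 & u < pos_freq)
  neg <- as.integer(ub_prev == 1 & u < neg_freq)
  list(pos = pos, neg = neg)
}

#' Advance the site by one day
#'
#' Executes the daily loop: (1) the site-wide meeting draw; (2) per-worker
#' communication and feedback draws; (3) awareness/knowledge recomputation
#' for the day; (4) foreman norm updates and cognition (foremen act
#' first); (5) worker norm updates (foreman observations are same-day,
#' coworker observations previous-day), risk acceptance, and cognition;
#' (6) attitude updates; (7) a record row per agent. On day 1 there is no
#' previous behavior to react to, so norms keep their initial values and
#' no feedback is drawn.
#'
#' The random draw order within a day is fixed: meeting (1 uniform);
#' worker coworker-communication counts (binomial) and foreman-communication
#' indicators; then, from day 2 on, foreman-feedback and manager-feedback
#' uniforms for workers and manager-feedback uniforms for foremen; foreman
#' manager-norm and crew-observation uniforms; foreman residual, actual
#' risk, detection and outcome draws; worker foreman-demonstration,
#' foreman-feedback, manager-feedback and coworker-observation uniforms;
#' worker residual, actual risk, detection and outcome draws. All blocks
#' are laid out agent-major in crew/index order.
#'
#' @param state an `sc_state` from [init_population()].
#' @param cfg the matching `sc_config`.
#' @return List with elements `state` (advanced) and `records` (a numeric
#'   matrix, one row per agent, workers first).
#' @export
step_day <- function(state, cfg) {
  t <- state$day + 1L
  n_w <- state$n_w; n_f <- state$n_f
  w <- state$workers; f <- state$foremen
  wts <- cfg$norm_weights
  m <- cfg$memory_m; d <- cfg$demo_share_d
  ff <- cfg$feedback_freqs

  ## (1)-(2) interaction draws
  ia <- draw_interactions(state, cfg)
  st <- ia$st; cn1 <- ia$cn1; cn2 <- ia$cn2

  if (t > 1L) {
    fb_f <- draw_feedback_flags(w$ub_prev, ff[["foreman_pos"]],
                                ff[["foreman_neg"]], stats::runif(n_w))
    fb_m <- draw_feedback_flags(w$ub_prev, ff[["manager_pos"]],
                                ff[["manager_neg"]], stats::runif(n_w))
    fb_mf <- draw_feedback_flags(f$ub_prev, ff[["manager_pos"]],
                                 ff[["manager_neg"]], stats::runif(n_f))
  } else {
    fb_f <- fb_m <- list(pos = integer(n_w), neg = integer(n_w))
    fb_mf <- list(pos = integer(n_f), neg = integer(n_f))
  }

  ## (3) awareness / knowledge for the day
  cn_w <- cbind(cn1, cn2, st)
  sa_base_w <- if (cfg$sa_cumulative) w$sa_prev else cfg$sa0
  kl_base_w <- if (cfg$sa_cumulative) w$kl_prev else cfg$kl0
  sa_w <- update_awareness(sa_base_w, cn_w, cfg$ci_awareness)
  kl_w <- update_knowledge(kl_base_w, cn_w, cfg$ci_knowledge)
  cn_f <- cbind(integer(n_f), ia$cn2_f, st)
  sa_base_f <- if (cfg$sa_cumulative) f$sa_prev else cfg$sa0
  kl_base_f <- if (cfg$sa_cumulative) f$kl_prev else cfg$kl0
  sa_f <- update_awareness(sa_base_f, cn_f, cfg$ci_awareness)
  kl_f <- update_knowledge(kl_base_f, cn_f, cfg$ci_knowledge)

  ## (4) foremen: norm updates, then cognition
  if (t > 1L) {
    pma_f <- perceive_feedback(f$mn, f$ub_prev, f$ur_prev,
                               fb_mf$pos, fb_mf$neg, stats::runif(n_f))
    f$mn <- update_manager_norm(f$mn, pma_f, m)
    u_pwn <- matrix(stats::runif(n_f * state$wpg), n_f, state$wpg)
    pra <- perceive_demonstration(w$ar_prev[state$obs_f],
                                  w$ub_prev[state$obs_f], u_pwn)
    dim(pra) <- dim(u_pwn)
    s <- rowMeans(pra)
    f$wn <- if (cfg$coworker_memory_harmonized) (1 - m) * f$wn + m * s
            else m * f$wn + (1 - m) * s
  }
  eps_f <- r_dist(n_f, cfg$epsilon)
  ar_f <- r_dist(n_f, cfg$actual_risk)
  u_fr_f <- stats::runif(n_f)
  fwts <- state$foreman_weights
  ra_f <- compute_risk_acceptance(f$at, f$wn, 0, f$mn, state$foreman_w,
                                  fwts, eps_f)
  if (t > 1L) {
    f$p <- update_coeff(f$p, f$at - f$at_lag, kl_f - f$kl_lag, cfg$a1, cfg$a2)
  }
  fr_f <- find_risk(sa_f, kl_f, u_fr_f)
  pr_f <- perceived_risk_vec(fr_f, ar_f, f, t, cfg)
  ur_f <- understand_risk(f$p, pr_f)
  ub_f <- decide_behavior(ra_f, ur_f)
  out_f <- resolve_outcome(ub_f, cfg$env_risk_er, stats::runif(n_f))

  ## (5) workers: norm updates, risk acceptance, cognition
  if (t > 1L) {
    pfra <- perceive_demonstration(ar_f[w$group], ub_f[w$group],
                                   stats::runif(n_w))
    pfa <- perceive_feedback(w$fn, w$ub_prev, w$ur_prev,
                             fb_f$pos, fb_f$neg, stats::runif(n_w))
    if (!identical(cfg$frozen_norm, "foreman"))
      w$fn <- update_foreman_norm(w$fn, pfra, pfa, m, d, cfg$demo_role_enabled)
    pma <- perceive_feedback(w$mn, w$ub_prev, w$ur_prev,
                             fb_m$pos, fb_m$neg, stats::runif(n_w))
    if (!identical(cfg$frozen_norm, "manager"))
      w$mn <- update_manager_norm(w$mn, pma, m)
    if (state$k_obs > 0 && !identical(cfg$frozen_norm, "coworker")) {
      u_pra <- matrix(stats::runif(n_w * state$k_obs), n_w, state$k_obs)
      praw <- perceive_demonstration(w$ar_prev[state$obs_w],
                                     w$ub_prev[state$obs_w], u_pra)
      dim(praw) <- dim(u_pra)
      sw <- rowMeans(praw)
      w$wn <- if (cfg$coworker_memory_harmonized) (1 - m) * w$wn + m * sw
              else m * w$wn + (1 - m) * sw
    }
  }
  eps_w <- r_dist(n_w, cfg$epsilon)
  ar_w <- r_dist(n_w, cfg$actual_risk)
  u_fr_w <- stats::runif(n_w)
  ra_w <- compute_risk_acceptance(w$at, w$wn, w$fn, w$mn,
                                  cfg$social_identity_w, wts, eps_w)
  if (t > 1L) {
    w$p <- update_coeff(w$p, w$at - w$at_lag, kl_w - w$kl_lag, cfg$a1, cfg$a2)
  }
  fr_w <- find_risk(sa_w, kl_w, u_fr_w)
  pr_w <- perceived_risk_vec(fr_w, ar_w, w, t, cfg)
  ur_w <- understand_risk(w$p, pr_w)
  ub_w <- decide_behavior(ra_w, ur_w)
  out_w <- resolve_outcome(ub_w, cfg$env_risk_er, stats::runif(n_w))

  ## (6) attitude updates (optional extra shift on any feedback day)
  fb_any_w <- pmin(1L, fb_f$pos + fb_f$neg + fb_m$pos + fb_m$neg)
  old_at_w <- w$at
  w$at <- update_attitude(w$at, ub_w, out_w$accident, cfg$c1, cfg$c2) -
    cfg$feedback_attitude_shift * fb_any_w
  w$at <- pmin(1, pmax(0, w$at))
  w$at_lag <- old_at_w
  fb_any_f <- pmin(1L, fb_mf$pos + fb_mf$neg)
  old_at_f <- f$at
  f$at <- update_attitude(f$at, ub_f, out_f$accident, cfg$c1, cfg$c2) -
    cfg$feedback_attitude_shift * fb_any_f
  f$at <- pmin(1, pmax(0, f$at))
  f$at_lag <- old_at_f

  ## roll state forward
  w$kl_lag <- kl_w; f$kl_lag <- kl_f
  w$sa_prev <- sa_w; f$sa_prev <- sa_f
  w$kl_prev <- kl_w; f$kl_prev <- kl_f
  w$pr_sum <- w$pr_sum + pr_w
  w$pr_nzsum <- w$pr_nzsum + pr_w
  w$pr_nzcnt <- w$pr_nzcnt + (pr_w > 0)
  f$pr_sum <- f$pr_sum + pr_f
  f$pr_nzsum <- f$pr_nzsum + pr_f
  f$pr_nzcnt <- f$pr_nzcnt + (pr_f > 0)
  w$ub_prev <- ub_w; w$ur_prev <- ur_w; w$ar_prev <- ar_w
  f$ub_prev <- ub_f; f$ur_prev <- ur_f; f$ar_prev <- ar_f
  f$ub_today <- ub_f; f$ar_today <- ar_f

  state$workers <- w
  state$foremen <- f
  state$day <- t

  recs <- rbind(
    cbind(day = t, id = seq_len(n_w), group = w$group, is_foreman = 0,
          FR = fr_w, AR = ar_w, PR = pr_w, UR = ur_w, RA = ra_w, UB = ub_w,
          accident = out_w$accident, near_miss = out_w$near_miss,
          AT = old_at_w, SA = sa_w, KL = kl_w,
          WN = w$wn, FN = w$fn, MN = w$mn,
          CN1 = cn1, CN2 = cn2, CN3 = st,
          PFF = fb_f$pos, FF = fb_f$neg, PMF = fb_m$pos, MF = fb_m$neg),
    cbind(day = t, id = n_w + seq_len(n_f), group = f$group, is_foreman = 1,
          FR = fr_f, AR = ar_f, PR = pr_f, UR = ur_f, RA = ra_f, UB = ub_f,
          accident = out_f$accident, near_miss = out_f$near_miss,
          AT = old_at_f, SA = sa_f, KL = kl_f,
          WN = f$wn, FN = NA_real_, MN = f$mn,
          CN1 = 0, CN2 = ia$cn2_f, CN3 = st,
          PFF = NA_real_, FF = NA_real_, PMF = fb_mf$pos, MF = fb_mf$neg)
  )
  list(state = state, records = recs)
}

# vectorized perception with running-history bookkeeping held in the
# agent table (ag): day-1 empty history falls back to the actual risk
perceived_risk_vec <- function(fr, ar, ag, t, cfg) {
  lam <- cfg$lambda_perception
  if (t == 1L) return(ifelse(fr == 1, ar, 0))
  if (cfg$pr_history_exclude_zeros) {
    histmean <- ifelse(ag$pr_nzcnt > 0, ag$pr_nzsum / pmax(1, ag$pr_nzcnt), NA)
    blended <- ifelse(is.na(histmean), ar, lam * histmean + (1 - lam) * ar)
  } else {
    blended <- lam * (ag$pr_sum / (t - 1)) + (1 - lam) * ar
  }
  ifelse(fr == 1, blended, 0)
}

#' Run a full simulation
#'
#' Initializes the population with `seed` and advances [step_day()] for
#' `cfg$n_days` days, collecting the full worker-day trace, daily
#' population aggregates, and pooled summary statistics.
#'
#' @param cfg an `sc_config`.
#' @param seed integer seed (the reproducibility contract: identical
#'   `(cfg, seed)` give identical results, byte for byte).
#' @param keep_records keep the full per-agent daily trace (set `FALSE`
#'   for large replicate batches; summaries and aggregates are kept
#'   either way).
#' @return An object of class `sc_run`: list with `config`, `seed`,
#'   `records` (data.frame or `NULL`), `daily` (data.frame of per-day
#'   population aggregates over workers), and `summary` (see
#'   [run_summary()]).
#' @export
run_simulation <- function(cfg, seed = 1L, keep_records = TRUE) {
  validate_config(cfg)
  state <- init_population(cfg, seed = seed)
  n_days <- cfg$n_days
  n_w <- state$n_w; n_f <- state$n_f
  n_ag <- n_w + n_f
  trace <- if (keep_records && n_days > 0)
    matrix(NA_real_, nrow = n_days * n_ag, ncol = 25) else NULL

  daily <- matrix(NA_real_, nrow = n_days, ncol = 13,
                  dimnames = list(NULL, c(
                    "day", "unsafe_ratio", "mean_ra", "mean_at", "mean_wn",
                    "mean_fn", "mean_mn", "mean_sa", "mean_kl", "mean_comm",
                    "training", "accidents", "near_misses")))
  # sufficient statistics over worker-days for the validation fits
  acc <- list(n = 0, ub = 0, accid = 0, nm = 0,
              sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0,        # (AT, RA)
              c2x = 0, c2xx = 0, c2xy = 0,                       # (CN2, SA)
              c3x = 0, c3xx = 0, c3xy = 0,                       # (CN3, SA)
              cax = 0, caxx = 0, caxy = 0,                       # (CN1+CN2, SA)
              say = 0, sayy = 0)
  colnames_rec <- NULL
  for (t in seq_len(n_days)) {
    out <- step_day(state, cfg)
    state <- out$state
    rec <- out$records
    if (is.null(colnames_rec)) colnames_rec <- colnames(rec)
    if (!is.null(trace)) trace[((t - 1) * n_ag + 1):(t * n_ag), ] <- rec

    wrow <- rec[seq_len(n_w), , drop = FALSE]
    daily[t, ] <- c(t,
                    mean(wrow[, "UB"]), mean(wrow[, "RA"]), mean(wrow[, "AT"]),
                    mean(wrow[, "WN"]), mean(wrow[, "FN"]), mean(wrow[, "MN"]),
                    mean(wrow[, "SA"]), mean(wrow[, "KL"]),
                    mean(wrow[, "CN1"] + wrow[, "CN2"]), wrow[1, "CN3"],
                    sum(wrow[, "accident"]), sum(wrow[, "near_miss"]))
    if (cfg$include_foremen_in_ratio) {
      daily[t, "unsafe_ratio"] <- mean(rec[, "UB"])
      daily[t, "accidents"] <- sum(rec[, "accident"])
      daily[t, "near_misses"] <- sum(rec[, "near_miss"])
    }
    scope <- if (cfg$include_foremen_in_ratio) rec else wrow
    x <- scope[, "AT"]; y <- scope[, "RA"]
    sa <- scope[, "SA"]; c2 <- scope[, "CN2"]; c3 <- scope[, "CN3"]
    ca <- scope[, "CN1"] + c2
    acc$n <- acc$n + nrow(scope)
    acc$ub <- acc$ub + sum(scope[, "UB"])
    acc$accid <- acc$accid + sum(scope[, "accident"])
    acc$nm <- acc$nm + sum(scope[, "near_miss"])
    acc$sx <- acc$sx + sum(x); acc$sy <- acc$sy + sum(y)
    acc$sxx <- acc$sxx + sum(x * x); acc$syy <- acc$syy + sum(y * y)
    acc$sxy <- acc$sxy + sum(x * y)
    acc$say <- acc$say + sum(sa); acc$sayy <- acc$sayy + sum(sa * sa)
    acc$c2x <- acc$c2x + sum(c2); acc$c2xx <- acc$c2xx + sum(c2 * c2)
    acc$c2xy <- acc$c2xy + sum(c2 * sa)
    acc$c3x <- acc$c3x + sum(c3); acc$c3xx <- acc$c3xx + sum(c3 * c3)
    acc$c3xy <- acc$c3xy + sum(c3 * sa)
    acc$cax <- acc$cax + sum(ca); acc$caxx <- acc$caxx + sum(ca * ca)
    acc$caxy <- acc$caxy + sum(ca * sa)
  }

  records <- NULL
  if (!is.null(trace)) {
    colnames(trace) <- colnames_rec
    records <- as.data.frame(trace)
  }
  daily <- as.data.frame(daily)

  summary <- summarize_pooled(acc, daily, cfg)
  structure(list(config = cfg, seed = seed, records = records,
                 daily = daily, summary = summary),
            class = "sc_run")
}

# pooled summary statistics from the sufficient statistics
summarize_pooled <- function(acc, daily, cfg) {
  n <- acc$n
  n_scope <- cfg$n_groups * cfg$workers_per_group +
    if (cfg$include_foremen_in_ratio) cfg$n_groups else 0
  slope_stats <- function(sx, sxx, sxy, sy, syy) {
    vx <- n * sxx - sx^2
    vy <- n * syy - sy^2
    cv <- n * sxy - sx * sy
    if (n < 3 || vx <= 0 || vy <= 0)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r = NA_real_, r_squared = NA_real_))
    slope <- cv / vx
    list(slope = slope,
         intercept = (sy - slope * sx) / n,
         r = cv / sqrt(vx * vy),
         r_squared = (cv / sqrt(vx * vy))^2)
  }
  ols <- slope_stats(acc$sx, acc$sxx, acc$sxy, acc$sy, acc$syy)
  r_c2 <- slope_stats(acc$c2x, acc$c2xx, acc$c2xy, acc$say, acc$sayy)$r
  r_c3 <- slope_stats(acc$c3x, acc$c3xx, acc$c3xy, acc$say, acc$sayy)$r
  r_ca <- slope_stats(acc$cax, acc$caxx, acc$caxy, acc$say, acc$sayy)$r
  n_days <- nrow(daily)
  list(
    n_worker_days = n,
    unsafe_ratio = if (n > 0) acc$ub / n else NA_real_,
    accidents = acc$accid,
    near_misses = acc$nm,
    accident_rate = if (n > 0) 100 * acc$accid / n else NA_real_,
    accident_rate_run_total = if (n > 0)
      100 * acc$accid / n_scope else NA_real_,
    near_miss_to_accident = if (acc$accid > 0) acc$nm / acc$accid
                            else if (acc$nm > 0) Inf else NA_real_,
    first_day_unsafe = if (n_days > 0) daily$unsafe_ratio[1] else NA_real_,
    final_day_unsafe = if (n_days > 0) daily$unsafe_ratio[n_days] else NA_real_,
    attitude_ra_slope = ols$slope,
    attitude_ra_intercept = ols$intercept,
    attitude_ra_r_squared = ols$r_squared,
    r_comm_awareness = r_c2,
    r_training_awareness = r_c3,
    r_allcomm_awareness = r_ca
  )
}

#' Pooled summary of a run
#'
#' @param run an `sc_run`.
#' @return Named list of replicate-level statistics: pooled
#'   unsafe-behavior ratio, accident counts and rate (per 100 workers per
#'   day, plus the per-run-total alternative), near-miss:accident ratio,
#'   first/final-day unsafe ratios, the attitude-to-risk-acceptance OLS
#'   fit, and worker-day Pearson correlations of the interaction channels
#'   with safety awareness.
#' @export
run_summary <- function(run) {
  stopifnot(inherits(run, "sc_run"))
  run$summary
}

#' Run replicates
#'
#' Runs `n_runs` independent replicates; replicate `k` uses seed
#' `base_seed + k - 1`. Traces are dropped by default; summaries and
#' daily aggregates are kept.
#'
#' @param cfg an `sc_config`.
#' @param n_runs number of replicates (>= 1).
#' @param base_seed base seed.
#' @param keep_records keep full traces (memory-hungry).
#' @return An object of class `sc_replicates`: list of `sc_run`.
#' @export
run_replicates <- function(cfg, n_runs = 100L, base_seed = 1L,
                           keep_records = FALSE) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(k) {
    run_simulation(cfg, seed = base_seed + k - 1L, keep_records = keep_records)
  })
  structure(runs, class = "sc_replicates")
}

#' Per-replicate summary table
#'
#' @param reps an `sc_replicates`.
#' @return data.frame with one row per replicate and the [run_summary()]
#'   scalars as columns.
#' @export
replicate_summary <- function(reps) {
  stopifnot(inherits(reps, "sc_replicates"))
  do.call(rbind, lapply(reps, function(r) {
    s <- r$summary
    data.frame(seed = r$seed, unsafe_ratio = s$unsafe_ratio,
               accident_rate = s$accident_rate,
               accidents = s$accidents, near_misses = s$near_misses,
               near_miss_to_accident = s$near_miss_to_accident,
               first_day_unsafe = s$first_day_unsafe,
               final_day_unsafe = s$final_day_unsafe,
               attitude_ra_slope = s$attitude_ra_slope,
               r_comm_awareness = s$r_comm_awareness,
               r_training_awareness = s$r_training_awareness)
  }))
}

#' Write a run trace to CSV with a JSON metadata sidecar
#'
#' @param run an `sc_run` with records kept.
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  stopifnot(inherits(run, "sc_run"))
  if (is.null(run$records)) stop("run has no records (keep_records = FALSE)")
  utils::write.csv(run$records, path, row.names = FALSE)
  meta <- list(seed = run$seed,
               package_version = as.character(utils::packageVersion("sociocog")),
               config = unclass(run$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
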