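# Straight-line reference implementation of the daily model, written as
# explicit per-agent loops over the scalar equations. It consumes the
# same documented random stream as the engine (same draw blocks in the
# same order), so with a common seed it must reproduce the engine's trace
# exactly. Used on tiny instances (1 crew, a few workers, a few days).

oracle_qtri <- function(u, low, mode, high) {
  w <- high - low
  fm <- (mode - low) / w
  if (u < fm) low + sqrt(u * w * (mode - low))
  else high - sqrt((1 - u) * w * (high - mode))
}

oracle_draw <- function(d) {
  u <- runif(1)
  if (d$kind == "uniform") d$low + u * (d$high - d$low)
  else oracle_qtri(u, d$low, d$mode, d$high)
}

oracle_run <- function(cfg, seed) {
  set.seed(seed)
  n_f <- cfg$n_groups
  wpg <- cfg$workers_per_group
  n_w <- n_f * wpg
  stopifnot(n_f == 1)  # keep the stream layout trivially loopable
  k_obs <- if (is.null(cfg$k_observed)) wpg - 1L else cfg$k_observed
  a <- cfg$norm_weights[["coworker"]]
  b <- cfg$norm_weights[["foreman"]]
  cc <- cfg$norm_weights[["manager"]]
  wsi <- cfg$social_identity_w
  m <- cfg$memory_m; dd <- cfg$demo_share_d
  lam <- cfg$lambda_perception
  frz <- cfg$frozen_norm

  # initialization draws, same block order as the engine
  W <- list(at = numeric(n_w), p = numeric(n_w), wn = numeric(n_w),
            fn = numeric(n_w), mn = numeric(n_w))
  for (i in 1:n_w) W$at[i] <- oracle_draw(cfg$attitude_init)
  for (i in 1:n_w) W$p[i] <- oracle_draw(cfg$coeff_init)
  for (i in 1:n_w) W$wn[i] <- oracle_draw(cfg$attitude_init)
  for (i in 1:n_w) W$fn[i] <- oracle_draw(cfg$attitude_init)
  for (i in 1:n_w) W$mn[i] <- oracle_draw(cfg$attitude_init)
  Fm <- list(at = oracle_draw(cfg$attitude_init),
             p = oracle_draw(cfg$coeff_init),
             wn = oracle_draw(cfg$attitude_init),
             mn = oracle_draw(cfg$attitude_init))

  W$at_lag <- W$at; W$kl_lag <- rep(cfg$kl0, n_w)
  W$hist <- vector("list", n_w)
  W$ub_prev <- integer(n_w); W$ur_prev <- numeric(n_w)
  W$ar_prev <- numeric(n_w)
  Fm$at_lag <- Fm$at; Fm$kl_lag <- cfg$kl0
  Fm$hist <- list(numeric(0))
  Fm$ub_prev <- 0L; Fm$ur_prev <- 0; Fm$ar_prev <- 0

  fwsum <- a + cc
  fa <- a / fwsum; fc <- cc / fwsum

  clamp01 <- function(x) min(1, max(0, x))
  rows <- list()

  for (t in seq_len(cfg$n_days)) {
    st <- as.integer(runif(1) < cfg$training_freq)
    cn1 <- rbinom(n_w, cfg$k_comm_pool, cfg$comm_freq_coworker)
    cn2 <- integer(n_w)
    for (i in 1:n_w) cn2[i] <- as.integer(runif(1) < cfg$comm_freq_foreman)
    cn2f <- as.integer(runif(1) < cfg$comm_freq_foreman)

    pff <- ffn <- pmf <- mfn <- integer(n_w)
    pmf_f <- mf_f <- 0L
    if (t > 1) {
      for (i in 1:n_w) {
        u <- runif(1)
        if (W$ub_prev[i] == 0) pff[i] <- as.integer(u < cfg$feedback_freqs[["foreman_pos"]])
        else ffn[i] <- as.integer(u < cfg$feedback_freqs[["foreman_neg"]])
      }
      for (i in 1:n_w) {
        u <- runif(1)
        if (W$ub_prev[i] == 0) pmf[i] <- as.integer(u < cfg$feedback_freqs[["manager_pos"]])
        else mfn[i] <- as.integer(u < cfg$feedback_freqs[["manager_neg"]])
      }
      u <- runif(1)
      if (Fm$ub_prev == 0) pmf_f <- as.integer(u < cfg$feedback_freqs[["manager_pos"]])
      else mf_f <- as.integer(u < cfg$feedback_freqs[["manager_neg"]])
    }

    sa_w <- cfg$sa0 + cn1 * cfg$ci_awareness[1] + cn2 * cfg$ci_awareness[2] +
      st * cfg$ci_awareness[3]
    kl_w <- cfg$kl0 + cn1 * cfg$ci_knowledge[1] + cn2 * cfg$ci_knowledge[2] +
      st * cfg$ci_knowledge[3]
    sa_f <- cfg$sa0 + cn2f * cfg$ci_awareness[2] + st * cfg$ci_awareness[3]
    kl_f <- cfg$kl0 + cn2f * cfg$ci_knowledge[2] + st * cfg$ci_knowledge[3]

    ## foreman: norm updates, then cognition
    if (t > 1) {
      u <- runif(1)
      pma_f <- if (Fm$ub_prev == 0) {
        if (pmf_f == 1) u * Fm$ur_prev else Fm$mn
      } else {
        if (mf_f == 1) u * Fm$ur_prev else Fm$ur_prev + u * (1 - Fm$ur_prev)
      }
      Fm$mn <- (1 - m) * Fm$mn + m * pma_f
      pra <- numeric(wpg)
      for (i in 1:wpg) {
        u <- runif(1)
        pra[i] <- if (W$ub_prev[i] == 1) W$ar_prev[i] + u * (1 - W$ar_prev[i])
                  else u * W$ar_prev[i]
      }
      Fm$wn <- m * Fm$wn + (1 - m) * mean(pra)
    }
    eps_f <- oracle_draw(cfg$epsilon)
    ar_f <- oracle_draw(cfg$actual_risk)
    u_fr_f <- runif(1)
    ra_f <- clamp01((1 - wsi) * Fm$at + wsi * (fa * Fm$wn + fc * Fm$mn) + eps_f)
    if (t > 1)
      Fm$p <- max(0, Fm$p - cfg$a1 * (Fm$at - Fm$at_lag) +
                    cfg$a2 * (kl_f - Fm$kl_lag))
    fr_f <- as.integer(u_fr_f < min(1, sa_f * kl_f))
    pr_f <- if (fr_f == 0) 0
            else if (t == 1) ar_f
            else lam * mean(Fm$hist[[1]]) + (1 - lam) * ar_f
    ur_f <- Fm$p * pr_f
    ub_f <- as.integer(ra_f > ur_f)
    u_out <- runif(1)
    acc_f <- as.integer(ub_f == 1 && u_out < cfg$env_risk_er)
    nm_f <- as.integer(ub_f == 1 && acc_f == 0)

    ## workers: norm updates, then cognition
    if (t > 1) {
      pfra <- pfa <- pma <- numeric(n_w)
      for (i in 1:n_w) {
        u <- runif(1)
        pfra[i] <- if (ub_f == 1) ar_f + u * (1 - ar_f) else u * ar_f
      }
      for (i in 1:n_w) {
        u <- runif(1)
        pfa[i] <- if (W$ub_prev[i] == 0) {
          if (pff[i] == 1) u * W$ur_prev[i] else W$fn[i]
        } else {
          if (ffn[i] == 1) u * W$ur_prev[i]
          else W$ur_prev[i] + u * (1 - W$ur_prev[i])
        }
      }
      if (frz != "foreman") {
        for (i in 1:n_w) {
          sig <- if (cfg$demo_role_enabled) dd * pfra[i] + (1 - dd) * pfa[i]
                 else pfa[i]
          W$fn[i] <- (1 - m) * W$fn[i] + m * sig
        }
      }
      for (i in 1:n_w) {
        u <- runif(1)
        pma[i] <- if (W$ub_prev[i] == 0) {
          if (pmf[i] == 1) u * W$ur_prev[i] else W$mn[i]
        } else {
          if (mfn[i] == 1) u * W$ur_prev[i]
          else W$ur_prev[i] + u * (1 - W$ur_prev[i])
        }
      }
      if (frz != "manager")
        for (i in 1:n_w) W$mn[i] <- (1 - m) * W$mn[i] + m * pma[i]
      if (k_obs > 0 && frz != "coworker") {
        # u matrix is laid out worker-major per observation slot
        umat <- matrix(runif(n_w * k_obs), n_w, k_obs)
        for (i in 1:n_w) {
          mates <- setdiff(1:n_w, i)[1:k_obs]
          praw <- numeric(k_obs)
          for (j in 1:k_obs) {
            k <- mates[j]; u <- umat[i, j]
            praw[j] <- if (W$ub_prev[k] == 1) W$ar_prev[k] + u * (1 - W$ar_prev[k])
                       else u * W$ar_prev[k]
          }
          W$wn[i] <- m * W$wn[i] + (1 - m) * mean(praw)
        }
      }
    }
    eps_w <- ar_w <- u_fr_w <- numeric(n_w)
    for (i in 1:n_w) eps_w[i] <- oracle_draw(cfg$epsilon)
    for (i in 1:n_w) ar_w[i] <- oracle_draw(cfg$actual_risk)
    for (i in 1:n_w) u_fr_w[i] <- runif(1)
    ra_w <- fr_w <- pr_w <- ur_w <- ub_w <- acc_w <- nm_w <- numeric(n_w)
    for (i in 1:n_w) {
      ra_w[i] <- clamp01((1 - wsi) * W$at[i] +
                           wsi * (a * W$wn[i] + b * W$fn[i] + cc * W$mn[i]) +
                           eps_w[i])
      if (t > 1)
        W$p[i] <- max(0, W$p[i] - cfg$a1 * (W$at[i] - W$at_lag[i]) +
                        cfg$a2 * (kl_w[i] - W$kl_lag[i]))
      fr_w[i] <- as.integer(u_fr_w[i] < min(1, sa_w[i] * kl_w[i]))
      pr_w[i] <- if (fr_w[i] == 0) 0
                 else if (t == 1) ar_w[i]
                 else lam * mean(W$hist[[i]]) + (1 - lam) * ar_w[i]
      ur_w[i] <- W$p[i] * pr_w[i]
      ub_w[i] <- as.integer(ra_w[i] > ur_w[i])
    }
    for (i in 1:n_w) {
      u <- runif(1)
      acc_w[i] <- as.integer(ub_w[i] == 1 && u < cfg$env_risk_er)
      nm_w[i] <- as.integer(ub_w[i] == 1 && acc_w[i] == 0)
    }

    at_rec_w <- W$at; at_rec_f <- Fm$at
    for (i in 1:n_w) {
      old <- W$at[i]
      if (ub_w[i] == 1)
        W$at[i] <- clamp01(W$at[i] + if (acc_w[i] == 1) -cfg$c1 else cfg$c2)
      W$at_lag[i] <- old
    }
    old <- Fm$at
    if (ub_f == 1)
      Fm$at <- clamp01(Fm$at + if (acc_f == 1) -cfg$c1 else cfg$c2)
    Fm$at_lag <- old

    W$kl_lag <- kl_w; Fm$kl_lag <- kl_f
    for (i in 1:n_w) W$hist[[i]] <- c(W$hist[[i]], pr_w[i])
    Fm$hist[[1]] <- c(Fm$hist[[1]], pr_f)
    W$ub_prev <- ub_w; W$ur_prev <- ur_w; W$ar_prev <- ar_w
    Fm$ub_prev <- ub_f; Fm$ur_prev <- ur_f; Fm$ar_prev <- ar_f

    rows[[t]] <- rbind(
      cbind(day = t, id = 1:n_w, group = 1, is_foreman = 0, FR = fr_w,
            AR = ar_w, PR = pr_w, UR = ur_w, RA = ra_w, UB = ub_w,
            accident = acc_w, near_miss = nm_w, AT = at_rec_w,
            SA = sa_w, KL = kl_w, WN = W$wn, FN = W$fn, MN = W$mn,
            CN1 = cn1, CN2 = cn2, CN3 = st,
            PFF = pff, FF = ffn, PMF = pmf, MF = mfn),
      cbind(day = t, id = n_w + 1, group = 1, is_foreman = 1, FR = fr_f,
            AR = ar_f, PR = pr_f, UR = ur_f, RA = ra_f, UB = ub_f,
            accident = acc_f, near_miss = nm_f, AT = at_rec_f,
            SA = sa_f, KL = kl_f, WN = Fm$wn, FN = NA_real_, MN = Fm$mn,
            CN1 = 0, CN2 = cn2f, CN3 = st,
            PFF = NA_real_, FF = NA_real_, PMF = pmf_f, MF = mf_f)
    )
  }
  as.data.frame(do.call(rbind, rows))
}

# small configuration used across engine tests
tiny_config <- function(n_days = 3, ...) {
  site_config(n_groups = 1, workers_per_group = 2, n_days = n_days,
              k_comm_pool = 1, ...)
}
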