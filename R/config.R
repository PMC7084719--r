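#' Site configuration
#'
#' Builds the full set of model constants for a simulated construction
#' site. The defaults are the published baseline: a site of 5 crews of 20
#' workers plus one foreman per crew, simulated for 280 working days, with
#' the empirically anchored interaction frequencies and norm weights. A
#' handful of constants the baseline leaves free (memory, demonstration
#' share, attitude increments, the environment hazard rate, ...) carry
#' documented defaults; see the package vignette for the rationale behind
#' each.
#'
#' @param n_groups number of work crews.
#' @param workers_per_group workers per crew (each crew also has a foreman).
#' @param n_days number of simulated days.
#' @param actual_risk distribution of the actual hazard level a worker
#'   faces each day ([dist_spec()], values in `[0, 1]`).
#' @param attitude_init distribution of initial safety attitude
#'   (0 = risk-averse, 1 = risk-seeking). Initial norm perceptions are
#'   drawn from the same interval.
#' @param coeff_init distribution of the initial risk-understanding
#'   coefficient `p` (`p < 1` = the worker tends to underestimate risk).
#' @param sa0 initial safety awareness level.
#' @param kl0 initial safety knowledge level.
#' @param social_identity_w weight `w` put on group norms versus own
#'   attitude when forming risk acceptance, in `[0, 1]`.
#' @param norm_weights named weights `(coworker, foreman, manager)` of the
#'   three norms inside the social term; must sum to 1.
#' @param feedback_freqs named per-day probabilities
#'   `(foreman_pos, foreman_neg, manager_pos, manager_neg)` of behavior
#'   feedback, conditioned on the previous day's behavior (positive
#'   feedback can follow a safe act, negative feedback an unsafe act).
#' @param training_freq per-day probability of a site-wide safety meeting.
#' @param comm_freq_coworker per-day probability of a safety conversation
#'   with each of `k_comm_pool` coworkers.
#' @param comm_freq_foreman per-day probability of a safety conversation
#'   with the crew foreman.
#' @param ci_awareness awareness gain per event for the three channels
#'   (coworker communication, foreman communication, training).
#' @param ci_knowledge knowledge gain per event, same channel order.
#' @param lambda_perception memory weight `lambda` in risk perception.
#' @param a1,a2 sensitivity of the understanding coefficient to day-on-day
#'   attitude and knowledge change.
#' @param a3,a4 weights of the legacy individual-mode risk acceptance
#'   (attitude and subjective norm); not used by the social model.
#' @param c1,c2 attitude decrement after an accident / increment after an
#'   unpunished unsafe act.
#' @param memory_m norm memory level `m` in `[0, 1]`.
#' @param demo_share_d share `d` of the demonstration channel (versus
#'   feedback) in the foreman norm.
#' @param epsilon distribution of the residual on risk acceptance
#'   (zero-centred).
#' @param env_risk_er probability that the work environment is in an
#'   unsafe state on a given day (an unsafe act then becomes an accident).
#' @param k_observed number of crew-mates observed per day; `NULL` means
#'   all of them.
#' @param k_comm_pool number of potential coworker conversation partners
#'   per day.
#' @param demo_role_enabled if `FALSE`, the foreman norm is updated from
#'   behavior feedback only (the demonstration channel is removed).
#' @param include_foremen_in_ratio include foremen's own acts in
#'   site-level behavior statistics (default: workers only).
#' @param pr_history_exclude_zeros drop non-detection days (perceived risk
#'   0) from the perception memory mean.
#' @param coworker_memory_harmonized put the memory weight of the coworker
#'   norm on the new observation (as in the other two norms) instead of on
#'   the previous value as published.
#' @param sa_cumulative accumulate awareness/knowledge gains over days
#'   instead of recomputing from baseline each day (sensitivity analysis
#'   only; diverges over long horizons).
#' @param feedback_attitude_shift optional attitude decrement applied on
#'   any feedback day (0 in the baseline).
#' @param frozen_norm sensitivity variant of the norm-exclusion
#'   experiments: the named norm (`"coworker"`, `"foreman"`,
#'   `"manager"`) keeps its weight in the risk-acceptance equation but is
#'   never updated after initialization, modelling a worker who stops
#'   perceiving that group. `"none"` (the default) disables it; the
#'   standard exclusion semantics is weight renormalization via
#'   [exclude_norm()].
#' @return A validated list of class `sc_config`.
#' @seealso [load_config()], [apply_scenario()]
#' @examples
#' cfg <- site_config(n_days = 10)
#' cfg$norm_weights
#' @export
site_config <- function(n_groups = 5,
                        workers_per_group = 20,
                        n_days = 280,
                        actual_risk = dist_spec("triangular", 0.1, 0.9, mode = 0.5),
                        attitude_init = dist_spec("uniform", 0.4, 0.9),
                        coeff_init = dist_spec("uniform", 0.6, 1.2),
                        sa0 = 0.8,
                        kl0 = 0.8,
                        social_identity_w = 0.5,
                        norm_weights = c(coworker = 0.2, foreman = 0.45, manager = 0.35),
                        feedback_freqs = c(foreman_pos = 0.1, foreman_neg = 0.6,
                                           manager_pos = 0.1, manager_neg = 0.6),
                        training_freq = 0.5,
                        comm_freq_coworker = 0.3,
                        comm_freq_foreman = 0.3,
                        ci_awareness = c(0.01, 0.2, 0.2),
                        ci_knowledge = c(0.01, 0.2, 0.1),
                        lambda_perception = 0.5,
                        a1 = 0.5, a2 = 0.5, a3 = 0.5, a4 = 0.5,
                        c1 = 0.15, c2 = 0.01,
                        memory_m = 0.5,
                        demo_share_d = 0.5,
                        epsilon = dist_spec("uniform", -0.01, 0.01),
                        env_risk_er = 0.10,
                        k_observed = NULL,
                        k_comm_pool = 5,
                        demo_role_enabled = TRUE,
                        include_foremen_in_ratio = FALSE,
                        pr_history_exclude_zeros = FALSE,
                        coworker_memory_harmonized = FALSE,
                        sa_cumulative = FALSE,
                        feedback_attitude_shift = 0,
                        frozen_norm = "none") {
  cfg <- list(
    n_groups = as.integer(n_groups),
    workers_per_group = as.integer(workers_per_group),
    n_days = as.integer(n_days),
    actual_risk = actual_risk,
    attitude_init = attitude_init,
    coeff_init = coeff_init,
    sa0 = sa0, kl0 = kl0,
    social_identity_w = social_identity_w,
    norm_weights = norm_weights,
    feedback_freqs = feedback_freqs,
    training_freq = training_freq,
    comm_freq_coworker = comm_freq_coworker,
    comm_freq_foreman = comm_freq_foreman,
    ci_awareness = as.numeric(ci_awareness),
    ci_knowledge = as.numeric(ci_knowledge),
    lambda_perception = lambda_perception,
    a1 = a1, a2 = a2, a3 = a3, a4 = a4,
    c1 = c1, c2 = c2,
    memory_m = memory_m,
    demo_share_d = demo_share_d,
    epsilon = epsilon,
    env_risk_er = env_risk_er,
    k_observed = if (is.null(k_observed)) NULL else as.integer(k_observed),
    k_comm_pool = as.integer(k_comm_pool),
    demo_role_enabled = isTRUE(demo_role_enabled),
    include_foremen_in_ratio = isTRUE(include_foremen_in_ratio),
    pr_history_exclude_zeros = isTRUE(pr_history_exclude_zeros),
    coworker_memory_harmonized = isTRUE(coworker_memory_harmonized),
    sa_cumulative = isTRUE(sa_cumulative),
    feedback_attitude_shift = as.numeric(feedback_attitude_shift),
    frozen_norm = match.arg(frozen_norm,
                            c("none", "coworker", "foreman", "manager"))
  )
  class(cfg) <- "sc_config"
  validate_config(cfg)
  cfg
}

#' Validate a site configuration
#'
#' Checks types, ranges and structural constraints (norm weights summing
#' to 1, probability fields in `[0, 1]`, ordered distribution bounds).
#' Errors name the offending key.
#'
#' @param cfg a configuration list.
#' @return The validated `sc_config`, invisibly usable in a pipeline.
#' @export
validate_config <- function(cfg) {
  chk_pos_int <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop(key, " must be a positive integer", call. = FALSE)
  }
  chk_prob <- function(key, v = cfg[[key]]) {
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
      stop(key, " must lie in [0, 1]", call. = FALSE)
  }
  chk_nonneg <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      stop(key, " must be nonnegative", call. = FALSE)
  }
  for (k in c("n_groups", "workers_per_group", "k_comm_pool")) chk_pos_int(k)
  if (cfg$n_days < 0 || cfg$n_days != round(cfg$n_days))
    stop("n_days must be a nonnegative integer", call. = FALSE)
  validate_dist(cfg$actual_risk, "actual_risk")
  validate_dist(cfg$attitude_init, "attitude_init")
  validate_dist(cfg$coeff_init, "coeff_init")
  validate_dist(cfg$epsilon, "epsilon")
  chk_prob("actual_risk", c(cfg$actual_risk$low, cfg$actual_risk$high))
  for (k in c("social_identity_w", "training_freq", "comm_freq_coworker",
              "comm_freq_foreman", "env_risk_er", "lambda_perception",
              "memory_m", "demo_share_d", "c1", "c2")) chk_prob(k)
  for (k in c("sa0", "kl0", "a1", "a2", "a3", "a4",
              "ci_awareness", "ci_knowledge")) chk_nonneg(k)
  w <- cfg$norm_weights
  if (length(w) != 3 || !all(c("coworker", "foreman", "manager") %in% names(w)))
    stop("norm_weights must name coworker, foreman and manager", call. = FALSE)
  if (any(w < 0)) stop("norm_weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12)
    stop("norm weights must sum to 1", call. = FALSE)
  f <- cfg$feedback_freqs
  need <- c("foreman_pos", "foreman_neg", "manager_pos", "manager_neg")
  if (length(f) != 4 || !all(need %in% names(f)))
    stop("feedback_freqs must name ", paste(need, collapse = ", "), call. = FALSE)
  chk_prob("feedback_freqs", f)
  if (length(cfg$ci_awareness) != 3 || length(cfg$ci_knowledge) != 3)
    stop("ci_awareness and ci_knowledge must each have 3 entries", call. = FALSE)
  if (!is.null(cfg$k_observed) &&
      (cfg$k_observed < 0 || cfg$k_observed > cfg$workers_per_group - 1))
    stop("k_observed must be between 0 and workers_per_group - 1", call. = FALSE)
  if (cfg$k_comm_pool > cfg$workers_per_group - 1)
    stop("k_comm_pool must not exceed workers_per_group - 1", call. = FALSE)
  invisible(cfg)
}

# keys allowed in a configuration file / sweep
config_keys <- function() {
  setdiff(names(formals(site_config)), character(0))
}

#' Load a site configuration from a JSON file
#'
#' The file is a flat JSON object of configuration keys; distributions are
#' written as `{"kind": "uniform", "low": ..., "high": ...}` or
#' `{"kind": "triangular", "low": ..., "mode": ..., "high": ...}`. Keys
#' omitted from the file are filled with the documented defaults; unknown
#' keys are an error. The packaged baseline lives at
#' `system.file("extdata", "baseline_config.json", package = "sociocog")`.
#'
#' @param path path to a JSON configuration file.
#' @return A validated `sc_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "baseline_config.json",
#'                                package = "sociocog"))
#' cfg$n_groups
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse configuration file: ", conditionMessage(e),
                         call. = FALSE))
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in c("actual_risk", "attitude_init", "coeff_init", "epsilon")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.list(raw[[k]])
  }
  for (k in c("norm_weights", "feedback_freqs")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(site_config, raw)
}

#' Write a site configuration to a JSON file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))`
#' reproduces `cfg` key for key.
#'
#' @param cfg an `sc_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  x$k_observed <- if (is.null(x$k_observed)) NULL else x$k_observed
  x$norm_weights <- as.list(x$norm_weights)
  x$feedback_freqs <- as.list(x$feedback_freqs)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Baseline configuration shipped with the package
#'
#' Convenience wrapper around [load_config()] for the packaged baseline
#' file.
#'
#' @return A validated `sc_config` with the baseline values.
#' @export
baseline_config <- function() {
  load_config(system.file("extdata", "baseline_config.json",
                          package = "sociocog", mustWork = TRUE))
}

#' Scenario specification
#'
#' Describes a scenario relative to a baseline configuration: which norm
#' (if any) to exclude from the risk-acceptance equation, whether the
#' foreman's demonstration channel is active, and which parameters to
#' sweep over which levels.
#'
#' @param excluded_norm one of `"none"`, `"coworker"`, `"foreman"`,
#'   `"manager"`.
#' @param demonstration_role_enabled keep the foreman demonstration
#'   channel?
#' @param swept_params named list mapping configuration keys to numeric
#'   level vectors; the Cartesian product of levels is expanded by
#'   [apply_scenario()].
#' @param n_replicates number of replicate runs the scenario asks for.
#' @param base_seed base seed; replicate `k` runs with `base_seed + k - 1`.
#' @return A list of class `sc_scenario`.
#' @export
scenario_spec <- function(excluded_norm = "none",
                          demonstration_role_enabled = TRUE,
                          swept_params = list(),
                          n_replicates = 1L,
                          base_seed = 1L) {
  excluded_norm <- match.arg(excluded_norm,
                             c("none", "coworker", "foreman", "manager"))
  if (length(swept_params) > 0) {
    if (is.null(names(swept_params)) || any(names(swept_params) == ""))
      stop("swept_params must be a named list", call. = FALSE)
    bad <- setdiff(names(swept_params), config_keys())
    if (length(bad) > 0)
      stop("swept parameter(s) not in the configuration: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(excluded_norm = excluded_norm,
                 demonstration_role_enabled = isTRUE(demonstration_role_enabled),
                 swept_params = swept_params,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "sc_scenario")
}

#' Exclude one norm from the risk-acceptance equation
#'
#' Sets the excluded norm's weight to zero and renormalizes the remaining
#' weights to sum to 1, mirroring the published exclusion variants of the
#' risk-acceptance equation.
#'
#' @param cfg an `sc_config`.
#' @param which `"coworker"`, `"foreman"` or `"manager"`.
#' @return The modified configuration.
#' @examples
#' cfg <- site_config()
#' exclude_norm(cfg, "foreman")$norm_weights
#' @export
exclude_norm <- function(cfg, which) {
  which <- match.arg(which, c("coworker", "foreman", "manager"))
  w <- cfg$norm_weights
  rest <- sum(w[setdiff(names(w), which)])
  if (rest <= 0)
    stop("cannot exclude the only norm with nonzero weight", call. = FALSE)
  w[which] <- 0
  w <- w / sum(w)
  cfg$norm_weights <- w
  validate_config(cfg)
  cfg
}

#' Expand a scenario into configuration variants
#'
#' Applies the norm exclusion and demonstration switch of `spec` to `cfg`,
#' then expands the Cartesian product of any swept parameter levels. With
#' no exclusion and no sweep the result is a single variant identical to
#' `cfg`. Every variant passes the same validation as a hand-written
#' configuration.
#'
#' @param cfg an `sc_config` baseline.
#' @param spec an [scenario_spec()].
#' @return A list of `sc_config` variants; the swept levels of variant `i`
#'   are attached as `attr(x[[i]], "levels")`.
#' @export
apply_scenario <- function(cfg, spec) {
  validate_config(cfg)
  stopifnot(inherits(spec, "sc_scenario"))
  base <- cfg
  if (spec$excluded_norm != "none") base <- exclude_norm(base, spec$excluded_norm)
  base$demo_role_enabled <- spec$demonstration_role_enabled
  if (length(spec$swept_params) == 0) {
    validate_config(base)
    return(list(base))
  }
  grid <- expand.grid(spec$swept_params, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- base
    for (p in names(grid)) v[[p]] <- grid[i, p]
    validate_config(v)
    attr(v, "levels") <- as.list(grid[i, , drop = FALSE])
    v
  })
}
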