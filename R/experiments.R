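# map a management-lever name to a configuration modification; a raw
# configuration key is also accepted
sweepable_params <- function() {
  c("manager_feedback", "foreman_feedback", "foreman_comm",
    "training", "social_identity")
}

set_sweep_level <- function(cfg, param, level) {
  switch(param,
    manager_feedback = {
      cfg$feedback_freqs[["manager_pos"]] <- level
      cfg$feedback_freqs[["manager_neg"]] <- level
      cfg
    },
    foreman_feedback = {
      cfg$feedback_freqs[["foreman_pos"]] <- level
      cfg$feedback_freqs[["foreman_neg"]] <- level
      cfg
    },
    foreman_comm = { cfg$comm_freq_foreman <- level; cfg },
    training = { cfg$training_freq <- level; cfg },
    social_identity = { cfg$social_identity_w <- level; cfg },
    {
      if (!param %in% config_keys()) stop("unknown parameter: ", param)
      cfg[[param]] <- level
      cfg
    })
}

#' Norm-exclusion experiment table
#'
#' Runs the baseline and the four exclusion variants — manager norm,
#' coworker norm, foreman norm, and the foreman demonstration role
#' (foreman norm from feedback only) — for `n_replicates` replicates
#' each, using common random seeds across rows to sharpen the
#' between-scenario contrasts.
#'
#' Two exclusion semantics are available. `"renormalize"` (default)
#' removes the norm's term from the risk-acceptance equation and
#' renormalizes the remaining weights to sum to 1. `"freeze"` keeps the
#' weights but stops updating the excluded norm, so every worker carries
#' his initial perception of that group unchanged; see the vignette for
#' why the two variants answer different questions.
#'
#' @param cfg baseline `sc_config`.
#' @param n_replicates replicates per row.
#' @param base_seed base seed shared by all rows.
#' @param mode `"renormalize"` or `"freeze"` (demonstration-role removal
#'   is identical under both).
#' @return data.frame with one row per scenario: mean pooled
#'   unsafe-behavior ratio, mean accident rate, and percentage change of
#'   each relative to the baseline row.
#' @export
run_exclusion_table <- function(cfg, n_replicates = 100L, base_seed = 1L,
                                mode = c("renormalize", "freeze")) {
  validate_config(cfg)
  mode <- match.arg(mode)
  variant <- function(which) {
    if (mode == "renormalize") exclude_norm(cfg, which)
    else { v <- cfg; v$frozen_norm <- which; v }
  }
  variants <- list(
    baseline = cfg,
    exclude_manager = variant("manager"),
    exclude_coworker = variant("coworker"),
    exclude_foreman = variant("foreman"),
    exclude_demonstration = { v <- cfg; v$demo_role_enabled <- FALSE; v }
  )
  rows <- lapply(names(variants), function(nm) {
    reps <- run_replicates(variants[[nm]], n_runs = n_replicates,
                           base_seed = base_seed, keep_records = FALSE)
    tab <- replicate_summary(reps)
    data.frame(scenario = nm,
               unsafe_ratio = mean(tab$unsafe_ratio),
               accident_rate = mean(tab$accident_rate),
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  base <- out[out$scenario == "baseline", ]
  out$unsafe_ratio_change_pct <-
    100 * (out$unsafe_ratio - base$unsafe_ratio) / base$unsafe_ratio
  out$accident_rate_change_pct <-
    100 * (out$accident_rate - base$accident_rate) / base$accident_rate
  rownames(out) <- NULL
  out
}

#' Single-factor management sweep
#'
#' Sweeps one management lever over a grid of levels, all other
#' parameters held at baseline, with common random seeds across levels.
#' Levers: `"manager_feedback"` and `"foreman_feedback"` (set both the
#' positive and negative feedback probability of that role),
#' `"foreman_comm"`, `"training"`, `"social_identity"`; any scalar
#' configuration key is also accepted.
#'
#' @param cfg baseline `sc_config`.
#' @param param lever name.
#' @param levels numeric levels (default the published 11-level grid
#'   0, 0.1, ..., 1).
#' @param n_replicates replicates per level.
#' @param base_seed base seed shared by all cells.
#' @param statistic `"pooled"` (unsafe ratio over all days) or
#'   `"final_day"`.
#' @return data.frame of class `sc_sweep`: one row per level with the
#'   replicate-mean unsafe-behavior ratio and accident rate.
#' @export
sweep_single <- function(cfg, param, levels = seq(0, 1, by = 0.1),
                         n_replicates = 100L, base_seed = 1L,
                         statistic = c("pooled", "final_day")) {
  validate_config(cfg)
  statistic <- match.arg(statistic)
  rows <- lapply(levels, function(lv) {
    v <- validate_or_die(set_sweep_level(cfg, param, lv))
    reps <- run_replicates(v, n_runs = n_replicates, base_seed = base_seed,
                           keep_records = FALSE)
    tab <- replicate_summary(reps)
    data.frame(param = param, level = lv,
               unsafe_ratio = if (statistic == "pooled")
                 mean(tab$unsafe_ratio) else mean(tab$final_day_unsafe),
               accident_rate = mean(tab$accident_rate),
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sc_sweep", class(out))
  out
}

#' Paired-factor management sweep
#'
#' Full grid over two distinct levers; each cell is the replicate-mean
#' pooled unsafe-behavior ratio, common random seeds across cells.
#'
#' @param cfg baseline `sc_config`.
#' @param param_x,param_y two distinct lever names (see [sweep_single()]).
#' @param levels_x,levels_y level grids.
#' @param n_replicates replicates per cell.
#' @param base_seed base seed shared by all cells.
#' @param statistic see [sweep_single()].
#' @return data.frame of class `sc_sweep`: one row per level pair.
#' @export
sweep_paired <- function(cfg, param_x, param_y,
                         levels_x = seq(0, 1, by = 0.1),
                         levels_y = seq(0, 1, by = 0.1),
                         n_replicates = 100L, base_seed = 1L,
                         statistic = c("pooled", "final_day")) {
  validate_config(cfg)
  statistic <- match.arg(statistic)
  if (identical(param_x, param_y)) stop("param_x and param_y must differ")
  grid <- expand.grid(x = levels_x, y = levels_y, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- set_sweep_level(cfg, param_x, grid$x[i])
    v <- validate_or_die(set_sweep_level(v, param_y, grid$y[i]))
    reps <- run_replicates(v, n_runs = n_replicates, base_seed = base_seed,
                           keep_records = FALSE)
    tab <- replicate_summary(reps)
    data.frame(param_x = param_x, param_y = param_y,
               level_x = grid$x[i], level_y = grid$y[i],
               unsafe_ratio = if (statistic == "pooled")
                 mean(tab$unsafe_ratio) else mean(tab$final_day_unsafe),
               accident_rate = mean(tab$accident_rate),
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sc_sweep", class(out))
  out
}

validate_or_die <- function(cfg) {
  validate_config(cfg)
  cfg
}
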