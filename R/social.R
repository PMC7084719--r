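#' Safety awareness for the day
#'
#' Awareness is recomputed each day from the worker's baseline plus the
#' gains of that day's interaction events:
#' `SA = sa0 + sum_j cn_j * ci_j` over the three channels (coworker
#' communication, foreman communication, site training). Values above 1
#' are legal; only the detection probability is capped.
#'
#' @param sa0 baseline awareness.
#' @param cn event counts for the three channels; a vector of length 3,
#'   or an `n x 3` matrix for many agents.
#' @param ci per-event awareness gains (length 3).
#' @return Awareness level(s).
#' @examples
#' update_awareness(0.8, c(0, 1, 0), c(0.01, 0.2, 0.2))  # 1.0
#' @export
update_awareness <- function(sa0, cn, ci) {
  if (any(sa0 < 0) || any(cn < 0) || any(ci < 0)) stop("inputs must be nonnegative")
  if (is.matrix(cn)) sa0 + as.vector(cn %*% ci)
  else sa0 + sum(cn * ci)
}

#' Safety knowledge for the day
#'
#' Same structure as [update_awareness()] with the knowledge gains.
#'
#' @param kl0 baseline knowledge.
#' @param cn event counts (length 3, or `n x 3` matrix).
#' @param ci_k per-event knowledge gains (length 3).
#' @return Knowledge level(s).
#' @export
update_knowledge <- function(kl0, cn, ci_k) {
  update_awareness(kl0, cn, ci_k)
}

#' Demonstration perception
#'
#' Observing another agent's act is read as a noisy signal of that
#' agent's risk acceptance relative to the actual risk: an unsafe act is
#' perceived as acceptance uniformly above `ar`, a safe act as acceptance
#' uniformly below it.
#'
#' @param ar actual risk accompanying the observed act, in `[0, 1]`.
#' @param observed_ub observed behavior (0/1).
#' @param u uniform draw(s).
#' @return Perception value(s) in `[0, 1]`.
#' @export
perceive_demonstration <- function(ar, observed_ub, u) {
  if (any(ar < 0) || any(ar > 1)) stop("ar must lie in [0, 1]")
  n <- max(length(ar), length(observed_ub), length(u))
  ar <- rep_len(ar, n); observed_ub <- rep_len(observed_ub, n)
  u <- rep_len(u, n)
  ifelse(observed_ub == 1, ar + u * (1 - ar), u * ar)
}

#' Feedback perception
#'
#' How a worker reads the previous day's behavior feedback (from foreman
#' or manager) as that authority's risk acceptance:
#' * safe act, no positive feedback: the perceived norm carries over;
#' * safe act, positive feedback: acceptance below own risk understanding;
#' * unsafe act, negative feedback: acceptance below own risk
#'   understanding (the act was unacceptable);
#' * unsafe act, no negative feedback: acceptance above own risk
#'   understanding (tacit approval).
#'
#' @param prev_norm previous perceived norm, in `[0, 1]`.
#' @param ub_prev previous day's behavior (0/1).
#' @param ur_prev previous day's risk understanding.
#' @param got_positive positive-feedback flag (0/1).
#' @param got_negative negative-feedback flag (0/1).
#' @param u uniform draw(s).
#' @return Perception value(s).
#' @export
perceive_feedback <- function(prev_norm, ub_prev, ur_prev,
                              got_positive, got_negative, u) {
  n <- max(length(prev_norm), length(ub_prev), length(ur_prev),
           length(got_positive), length(got_negative), length(u))
  prev_norm <- rep_len(prev_norm, n); ub_prev <- rep_len(ub_prev, n)
  ur_prev <- rep_len(ur_prev, n)
  got_positive <- rep_len(got_positive, n)
  got_negative <- rep_len(got_negative, n)
  u <- rep_len(u, n)
  ifelse(ub_prev == 0,
         ifelse(got_positive == 1, u * ur_prev, prev_norm),
         ifelse(got_negative == 1, u * ur_prev, ur_prev + u * (1 - ur_prev)))
}

#' Foreman norm update
#'
#' The perceived foreman norm blends its previous value with today's
#' perception of the foreman's risk acceptance, which itself mixes the
#' demonstration channel (share `d`) and the feedback channel:
#' `FN = (1 - m) * FN_prev + m * (d * PFRA + (1 - d) * PFA)`. With the
#' demonstration role disabled the update uses feedback only.
#'
#' @param fn_prev previous foreman norm.
#' @param pfra demonstration perception.
#' @param pfa feedback perception.
#' @param m memory level in `[0, 1]`.
#' @param d demonstration share in `[0, 1]`.
#' @param demo_enabled demonstration channel active?
#' @return Updated foreman norm (vectorized).
#' @export
update_foreman_norm <- function(fn_prev, pfra, pfa, m, d, demo_enabled = TRUE) {
  sig <- if (isTRUE(demo_enabled)) d * pfra + (1 - d) * pfa else pfa
  (1 - m) * fn_prev + m * sig
}

#' Coworker norm update
#'
#' As published, the memory weight of the coworker norm sits on the
#' previous value — the opposite convention to the foreman and manager
#' norms: `WN = m * WN_prev + (1 - m) * mean(PRA)`. The
#' `harmonized` switch flips it to match the other two norms. An empty
#' observation list carries the previous value forward.
#'
#' @param wn_prev previous coworker norm.
#' @param pra_list demonstration perceptions of the observed coworkers.
#' @param m memory level.
#' @param harmonized use the foreman/manager memory convention instead.
#' @return Updated coworker norm (scalar).
#' @export
update_coworker_norm <- function(wn_prev, pra_list, m, harmonized = FALSE) {
  if (length(pra_list) == 0) return(wn_prev)
  s <- mean(pra_list)
  if (isTRUE(harmonized)) (1 - m) * wn_prev + m * s
  else m * wn_prev + (1 - m) * s
}

#' Manager norm update
#'
#' `MN = (1 - m) * MN_prev + m * PMA`, where `PMA` is the feedback
#' perception of the manager's risk acceptance (the manager has no
#' demonstration channel — site management is a policy, not an embodied
#' agent).
#'
#' @param mn_prev previous manager norm.
#' @param pma feedback perception.
#' @param m memory level.
#' @return Updated manager norm (vectorized).
#' @export
update_manager_norm <- function(mn_prev, pma, m) {
  (1 - m) * mn_prev + m * pma
}

#' Risk acceptance under social norms
#'
#' `RA = (1 - w) * AT + w * (a * WN + b * FN + c * MN) + eps`, clamped to
#' `[0, 1]`. `w` is the worker's social identity; `(a, b, c)` are the
#' coworker/foreman/manager norm weights (summing to 1, possibly after
#' renormalization under a norm exclusion); `eps` is a small residual.
#'
#' @param at attitude.
#' @param wn,fn,mn perceived coworker/foreman/manager norms.
#' @param w social identity in `[0, 1]`.
#' @param weights norm weights `(coworker, foreman, manager)` summing
#'   to 1.
#' @param eps residual draw(s).
#' @return Risk acceptance (vectorized).
#' @examples
#' compute_risk_acceptance(0.578, 0.305, 0.237, 0.150, 0.5,
#'                         c(coworker = 0.2, foreman = 0.45, manager = 0.35),
#'                         eps = 0.004)
#' @export
compute_risk_acceptance <- function(at, wn, fn, mn, w, weights, eps = 0) {
  if (abs(sum(weights) - 1) > 1e-12)
    stop("norm weights must sum to 1")
  ra <- (1 - w) * at +
    w * (weights[["coworker"]] * wn + weights[["foreman"]] * fn +
           weights[["manager"]] * mn) + eps
  pmin(1, pmax(0, ra))
}

#' Risk acceptance, individual mode
#'
#' Legacy formulation without explicit norm channels:
#' `RA = a3 * AT + a4 * SB` with `SB` an aggregate subjective norm. Not
#' used by the social baseline model; retained for comparison.
#'
#' @param at attitude.
#' @param sb subjective norm aggregate.
#' @param a3,a4 weights.
#' @return Risk acceptance (vectorized).
#' @export
compute_risk_acceptance_individual <- function(at, sb, a3, a4) {
  a3 * at + a4 * sb
}

#' Aggregate subjective norm
#'
#' Weighted combination of the three perceived norms,
#' `SB = a * WN + b * FN + c * MN`.
#'
#' @param wn,fn,mn perceived norms.
#' @param weights norm weights `(coworker, foreman, manager)`.
#' @return Subjective norm (vectorized).
#' @export
subjective_norm <- function(wn, fn, mn, weights) {
  weights[["coworker"]] * wn + weights[["foreman"]] * fn +
    weights[["manager"]] * mn
}
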