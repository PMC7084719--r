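#' Hazard detection
#'
#' First cognitive stage. A worker detects the day's hazard with
#' probability `min(1, sa * kl)`: detection requires both awareness (the
#' propensity to look) and knowledge (the ability to recognize what is
#' seen). The uniform draw is supplied by the caller so that the engine
#' owns the random stream.
#'
#' @param sa safety awareness level (>= 0, may exceed 1).
#' @param kl safety knowledge level (>= 0, may exceed 1).
#' @param u uniform draw(s) in `[0, 1)`.
#' @return Integer 0/1 vector: 1 = hazard found.
#' @examples
#' find_risk(0.8, 0.8, 0.5)   # 1, since 0.5 < 0.8 * 0.8
#' @export
find_risk <- function(sa, kl, u) {
  if (any(sa < 0) || any(kl < 0)) stop("sa and kl must be nonnegative")
  as.integer(u < pmin(1, sa * kl))
}

#' Risk perception
#'
#' Second-stage input: the hazard level a worker registers, blending the
#' memory of past perceptions with today's actual risk,
#' `PR = lambda * mean(history) + (1 - lambda) * AR` when the hazard was
#' found, and 0 otherwise. On the first day (empty history) the memory
#' term is undefined and perception equals the actual risk. By default
#' the history mean runs over all previous days including the zeros from
#' non-detection days; `exclude_zeros` drops them.
#'
#' @param history numeric vector of past perception values (may be empty).
#' @param ar today's actual risk in `[0, 1]`.
#' @param lam memory weight `lambda` in `[0, 1]`.
#' @param fr hazard-found indicator (0/1).
#' @param exclude_zeros drop zero entries from the history mean.
#' @return Perceived risk (scalar).
#' @export
perceive_risk <- function(history, ar, lam, fr, exclude_zeros = FALSE) {
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (fr == 0) return(0)
  h <- if (exclude_zeros) history[history != 0] else history
  if (length(h) == 0) return(ar)
  lam * mean(h) + (1 - lam) * ar
}

#' Update the risk-understanding coefficient
#'
#' `p` scales perceived into understood risk; `p < 1` means the worker
#' underestimates. A shift of attitude towards risk seeking
#' (`d_at > 0`) lowers `p`, a knowledge gain raises it:
#' `p = p_prev - a1 * d_at + a2 * d_kl`, floored at 0.
#'
#' @param p_prev previous coefficient.
#' @param d_at day-on-day attitude change.
#' @param d_kl day-on-day knowledge change.
#' @param a1,a2 sensitivities.
#' @return Updated coefficient (vectorized).
#' @export
update_coeff <- function(p_prev, d_at, d_kl, a1, a2) {
  pmax(0, p_prev - a1 * d_at + a2 * d_kl)
}

#' Risk understanding
#'
#' `UR = p * PR`: perceived risk scaled by the understanding coefficient.
#'
#' @param p understanding coefficient (>= 0).
#' @param pr perceived risk (>= 0).
#' @return Understood risk (vectorized).
#' @export
understand_risk <- function(p, pr) {
  if (any(p < 0) || any(pr < 0)) stop("p and pr must be nonnegative")
  p * pr
}

#' Behavior decision
#'
#' Third stage: the worker acts unsafely iff the risk he accepts exceeds
#' the risk he understands (`RA > UR`). The tie `RA == UR` resolves to
#' safe behavior.
#'
#' @param ra risk acceptance.
#' @param ur risk understanding.
#' @return Integer 0/1 vector: 1 = unsafe behavior.
#' @examples
#' decide_behavior(0.475, 0.343)  # 1
#' decide_behavior(0.403, 0.478)  # 0
#' @export
decide_behavior <- function(ra, ur) {
  as.integer(ra > ur)
}

#' Resolve the outcome of a day's act
#'
#' An unsafe act in an unsafe environment state (probability `er`) is an
#' accident; an unsafe act otherwise is a near miss; a safe act is
#' neither.
#'
#' @param ub behavior indicator (0/1).
#' @param er probability of an unsafe environment state, in `[0, 1]`.
#' @param u uniform draw(s).
#' @return List with integer vectors `accident` and `near_miss`.
#' @export
resolve_outcome <- function(ub, er, u) {
  if (er < 0 || er > 1) stop("er must lie in [0, 1]")
  accident <- as.integer(ub == 1 & u < er)
  near_miss <- as.integer(ub == 1 & accident == 0)
  list(accident = accident, near_miss = near_miss)
}

#' Attitude update from the day's consequence
#'
#' A punished gamble (unsafe act + accident) pushes attitude towards risk
#' aversion by `c1`; an unpunished one pushes it towards risk seeking by
#' `c2`; a safe act leaves it unchanged. The result is clamped to
#' `[0, 1]`.
#'
#' @param at attitude in `[0, 1]`.
#' @param ub behavior indicator (0/1).
#' @param accident accident indicator (0/1).
#' @param c1 decrement after an accident.
#' @param c2 increment after an accident-free unsafe act.
#' @return Updated attitude (vectorized).
#' @export
update_attitude <- function(at, ub, accident, c1, c2) {
  out <- at + ifelse(ub == 1, ifelse(accident == 1, -c1, c2), 0)
  pmin(1, pmax(0, out))
}
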