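#' Distribution specifications
#'
#' Model constants that are random at initialization (initial attitude,
#' initial risk-understanding coefficient) or per day (actual site risk,
#' the residual on risk acceptance) are described by small distribution
#' specification lists so they can round-trip through the JSON
#' configuration file. Two kinds are supported:
#'
#' * `list(kind = "uniform", low =, high =)`
#' * `list(kind = "triangular", low =, mode =, high =)`
#'
#' All sampling is done by inverse-CDF transform of `runif()` draws, so a
#' draw of `n` values always consumes exactly `n` uniforms from the R
#' random stream. This is part of the reproducibility contract: the
#' engine's documented draw order can be replayed by any straight-line
#' reimplementation that consumes uniforms in the same order.
#'
#' @param kind `"uniform"` or `"triangular"`.
#' @param low,high lower/upper bound.
#' @param mode mode of the triangular distribution (`low <= mode <= high`).
#' @return A distribution specification list.
#' @examples
#' dist_spec("triangular", 0.1, 0.9, mode = 0.5)
#' @export
dist_spec <- function(kind, low, high, mode = NULL) {
  kind <- match.arg(kind, c("uniform", "triangular"))
  d <- list(kind = kind, low = as.numeric(low), high = as.numeric(high))
  if (kind == "triangular") {
    if (is.null(mode)) stop("triangular distribution needs a mode")
    d <- list(kind = kind, low = as.numeric(low), mode = as.numeric(mode),
              high = as.numeric(high))
  }
  validate_dist(d)
  d
}

validate_dist <- function(d, name = "distribution") {
  if (!is.list(d) || is.null(d$kind))
    stop(name, ": not a distribution specification", call. = FALSE)
  if (!d$kind %in% c("uniform", "triangular"))
    stop(name, ": unknown distribution kind '", d$kind, "'", call. = FALSE)
  if (d$low > d$high)
    stop(name, ": bounds out of order (low > high)", call. = FALSE)
  if (d$kind == "triangular") {
    if (is.null(d$mode) || d$mode < d$low || d$mode > d$high)
      stop(name, ": triangular bounds must satisfy low <= mode <= high",
           call. = FALSE)
  }
  invisible(d)
}

#' Draw from a distribution specification
#'
#' Consumes exactly `n` uniforms from the current RNG stream (inverse-CDF
#' transform), regardless of `kind`.
#'
#' @param n number of draws.
#' @param d a [dist_spec()] list.
#' @return Numeric vector of length `n`.
#' @export
r_dist <- function(n, d) {
  u <- stats::runif(n)
  q_dist(u, d)
}

# inverse CDF, used both for sampling and in tests against closed forms
q_dist <- function(u, d) {
  if (d$kind == "uniform") {
    d$low + u * (d$high - d$low)
  } else {
    w <- d$high - d$low
    fm <- if (w > 0) (d$mode - d$low) / w else 0
    ifelse(u < fm,
           d$low + sqrt(u * w * (d$mode - d$low)),
           d$high - sqrt((1 - u) * w * (d$high - d$mode)))
  }
}

mean_dist <- function(d) {
  if (d$kind == "uniform") (d$low + d$high) / 2
  else (d$low + d$mode + d$high) / 3
}
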