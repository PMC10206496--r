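#' Clamp values into an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`; both bounds lie in `[0, 1]`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Derive a reproducible child seed for a named random stream
#'
#' One user-facing seed is expanded into independent per-stream seeds so that
#' the count sampler, the class assignment and the trajectory simulator can be
#' re-run (and tested) independently while staying deterministic.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return an integer seed in `[0, 2^31 - 2]`, a deterministic function of
#'   `(seed, stream)`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) * 7919 + sum(codes) * 104729
  as.integer((abs(seed) + h) %% (.Machine$integer.max - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
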