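#' Between-generation frequency map of a bias profile
#'
#' Across social cycles of aggregation-development-dispersal, a focal type at
#' frequency f contributes fraction f + B(f) of the next generation's spores,
#' so the minimal between-generation map is
#' \deqn{f' = clamp(f + B(f), 0, 1).}
#' Clamping makes 0 and 1 absorbing: an extinct type cannot recover. The map
#' composes spore formation only (no differential spore viability or
#' germination), matching a bias measured at the spore stage.
#'
#' @param profile a [bias_profile] (typically the corrected spore-bias
#'   profile).
#' @return an object of class `frequency_map`.
#' @export
frequency_map <- function(profile) {
  stopifnot(inherits(profile, "bias_profile"))
  structure(list(profile = profile), class = "frequency_map")
}

#' One application of a frequency map
#'
#' @param map a [frequency_map].
#' @param f frequencies in `[0, 1]` (vectorised).
#' @return `clamp(f + B(f), 0, 1)`.
#' @export
map_step <- function(map, f) {
  stopifnot(inherits(map, "frequency_map"))
  clamp(f + predict(map$profile, f))
}

#' Iterate a frequency map over social cycles
#'
#' @param map a [frequency_map].
#' @param f0 initial frequency in `[0, 1]`.
#' @param n_generations number of cycles (>= 0).
#' @return numeric vector of length `n_generations + 1`, starting at `f0`;
#'   never leaves `[0, 1]`.
#' @export
iterate_map <- function(map, f0, n_generations) {
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  stopifnot(n_generations >= 0)
  out <- numeric(n_generations + 1)
  out[1] <- f0
  f <- f0
  for (g in seq_len(n_generations)) {
    f <- map_step(map, f)
    out[g + 1] <- f
  }
  out
}

#' Fixed points of a frequency map, with stability and basins
#'
#' Fixed points satisfy B(f*) = 0. For the constrained cubic
#' B(f) = f(1-f)(a + b f) the endpoints 0 and 1 are always fixed, and the
#' unique possible interior fixed point is the root of a + b f = 0. Stability
#' follows the derivative criterion for one-dimensional maps: with
#' multiplier lambda = 1 + B'(f*), the point is stable if |lambda| < 1,
#' unstable if |lambda| > 1, and neutral if |lambda| = 1 within `tolerance`.
#' A stable interior fixed point is the coexistence equilibrium of the two
#' types. Basins of stable points extend to the neighbouring fixed points.
#'
#' @param map a [frequency_map].
#' @param tolerance half-width of the neutral band on `||lambda| - 1|`.
#' @return data.frame with columns `location`, `multiplier`
#'   (lambda = 1 + B'(f*)), `stability` (`stable`/`unstable`/`neutral`),
#'   `basin_lo`, `basin_hi` (NA for unstable/neutral points). For the
#'   degenerate profile B == 0 every frequency is fixed; the endpoints are
#'   reported as neutral and the attribute `degenerate` is `TRUE`.
#' @export
find_fixed_points <- function(map, tolerance = 1e-8) {
  stopifnot(inherits(map, "frequency_map"))
  prof <- map$profile
  a <- prof$a; b <- prof$b
  degenerate <- (a == 0 && b == 0)

  locs <- c(0, 1)
  if (!degenerate && b != 0) {
    root <- -a / b
    if (root > 0 && root < 1) locs <- sort(c(locs, root))
  }
  lambda <- 1 + profile_derivative(prof, locs)
  stability <- ifelse(abs(abs(lambda) - 1) <= tolerance, "neutral",
                      ifelse(abs(lambda) < 1, "stable", "unstable"))
  if (degenerate) stability[] <- "neutral"

  basin_lo <- rep(NA_real_, length(locs))
  basin_hi <- rep(NA_real_, length(locs))
  for (i in seq_along(locs)) {
    if (stability[i] != "stable") next
    basin_lo[i] <- if (i == 1) 0 else locs[i - 1]
    basin_hi[i] <- if (i == length(locs)) 1 else locs[i + 1]
  }
  structure(
    data.frame(location = locs, multiplier = lambda, stability = stability,
               basin_lo = basin_lo, basin_hi = basin_hi,
               stringsAsFactors = FALSE),
    degenerate = degenerate
  )
}

#' Classify social behavior along a frequency grid
#'
#' A focal type is a cheater at frequency f when its (corrected) spore bias
#' is positive there, a cooperator when negative, and neutral when the bias
#' is indistinguishable from 0. The neutral band is by preference tied to
#' measurement uncertainty: supply per-frequency confidence bounds and the
#' label is `neutral` wherever the interval covers 0. Without bounds, a fixed
#' `neutral_band` on |B| is used (default 0: strict sign).
#'
#' @param profile a [bias_profile].
#' @param frequencies grid of frequencies in `(0, 1)`.
#' @param lower,upper optional per-frequency confidence bounds on B(f)
#'   (vectors aligned with `frequencies`).
#' @param neutral_band non-negative scalar fallback noise floor on |B(f)|.
#' @return data.frame with columns `f`, `bias`, `behavior`
#'   (`cheater`/`cooperator`/`neutral`).
#' @export
classify_behavior <- function(profile, frequencies, lower = NULL,
                              upper = NULL, neutral_band = 0) {
  stopifnot(inherits(profile, "bias_profile"),
            all(frequencies > 0 & frequencies < 1))
  bias <- predict(profile, frequencies)
  if (!is.null(lower) || !is.null(upper)) {
    stopifnot(length(lower) == length(frequencies),
              length(upper) == length(frequencies))
    neutral <- lower <= 0 & upper >= 0
  } else {
    neutral <- abs(bias) <= neutral_band
  }
  behavior <- ifelse(neutral, "neutral",
                     ifelse(bias > 0, "cheater", "cooperator"))
  data.frame(f = frequencies, bias = bias, behavior = behavior,
             stringsAsFactors = FALSE)
}
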