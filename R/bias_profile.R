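#' Endpoint-constrained cubic bias profile
#'
#' A frequency-dependent bias profile B(f) constrained to vanish when either
#' population is absent, i.e. B(0) = B(1) = 0. The general cubic polynomial
#' satisfying both constraints is
#' \deqn{B(f) = f (1 - f) (a + b f),}
#' a two-parameter family spanned by the basis \{f(1-f), f^2(1-f)\}. The same
#' representation is used for the intrinsic fluorescent-label bias (estimated
#' from isogenic co-cultures) and for spore- or loner-bias profiles of
#' chimeras.
#'
#' @param a,b basis weights (dimensionless bias units).
#' @param rss residual sum of squares of the fit that produced the profile.
#' @param n_points number of (f, bias) points used in the fit.
#' @param samples optional character vector naming the samples the profile was
#'   fitted from (provenance).
#' @return an object of class `bias_profile`.
#' @export
bias_profile <- function(a, b, rss = NA_real_, n_points = NA_integer_,
                         samples = NULL) {
  stopifnot(is.finite(a), is.finite(b))
  structure(
    list(a = as.numeric(a), b = as.numeric(b), rss = as.numeric(rss),
         n_points = as.integer(n_points), samples = samples),
    class = "bias_profile"
  )
}

#' Evaluate a bias profile
#'
#' @param object a [bias_profile].
#' @param f frequencies in `[0, 1]` at which to evaluate B(f).
#' @param ... unused.
#' @return numeric vector of biases; exactly 0 at f = 0 and f = 1.
#' @export
predict.bias_profile <- function(object, f, ...) {
  f * (1 - f) * (object$a + object$b * f)
}

#' @export
print.bias_profile <- function(x, ...) {
  cat(sprintf("Constrained cubic bias profile: B(f) = f(1-f)(%.6g %+.6g f)\n",
              x$a, x$b))
  if (!is.na(x$rss))
    cat(sprintf("  fitted to %d points, RSS = %.4g\n", x$n_points, x$rss))
  invisible(x)
}

#' Derivative B'(f) of a bias profile
#'
#' Used by the stability analysis of the between-generation frequency map.
#'
#' @param profile a [bias_profile].
#' @param f frequencies.
#' @return numeric vector B'(f) = a + 2(b - a) f - 3 b f^2.
#' @export
profile_derivative <- function(profile, f) {
  profile$a + 2 * (profile$b - profile$a) * f - 3 * profile$b * f^2
}

#' Fit an endpoint-constrained cubic to (frequency, bias) points
#'
#' Least-squares fit of B(f) = f(1-f)(a + b f) to replicated, noisy bias
#' measurements. Because replicates make exact interpolation ill-posed, the
#' curve is fitted by (optionally weighted) ordinary least squares rather than
#' interpolated. The constraints B(0) = B(1) = 0 hold exactly by construction
#' of the basis.
#'
#' @param f frequencies in `[0, 1]`.
#' @param bias measured biases at those frequencies.
#' @param weights optional non-negative case weights (e.g. event counts).
#' @param samples optional character vector of sample ids (provenance).
#' @return a [bias_profile] with fit diagnostics.
#' @export
fit_constrained_cubic <- function(f, bias, weights = NULL, samples = NULL) {
  stopifnot(length(f) == length(bias))
  ok <- is.finite(f) & is.finite(bias)
  f <- f[ok]; bias <- bias[ok]
  if (!is.null(weights)) weights <- weights[ok]
  interior <- f > 0 & f < 1
  if (length(unique(f[interior])) < 2)
    stop("insufficient data: need at least 2 distinct interior frequencies (0 < f < 1)")
  x1 <- f * (1 - f)
  x2 <- f^2 * (1 - f)
  X <- cbind(x1, x2)
  fit <- if (is.null(weights)) stats::lm.fit(X, bias)
         else stats::lm.wfit(X, bias, w = weights)
  if (fit$rank < 2)
    stop("singular fit: design matrix for the constrained cubic is rank-deficient")
  cf <- fit$coefficients
  bias_profile(cf[[1]], cf[[2]],
               rss = sum(fit$residuals^2 * (weights %||% 1)),
               n_points = length(f), samples = samples)
}

#' Validate a label-bias model
#'
#' A label bias L(f) shifts the measured focal fraction from f to f + L(f);
#' since a fraction cannot leave `[0, 1]`, a physically admissible model must
#' satisfy |L(f)| <= min(f, 1 - f) everywhere. Checked on a dense grid.
#'
#' @param profile a [bias_profile] used as a label-bias model.
#' @param n_grid grid resolution.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_label_bias <- function(profile, n_grid = 1001) {
  stopifnot(inherits(profile, "bias_profile"))
  f <- seq(0, 1, length.out = n_grid)
  L <- predict(profile, f)
  bound <- pmin(f, 1 - f)
  bad <- abs(L) > bound + 1e-12
  if (any(bad))
    stop(sprintf(
      "invalid label-bias model: |L(f)| exceeds min(f, 1-f) at f = %.3f (L = %.4f)",
      f[which(bad)[1]], L[which(bad)[1]]))
  invisible(TRUE)
}
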