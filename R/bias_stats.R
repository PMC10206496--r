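#' Focal fraction of a two-colour count
#'
#' @param n_focal,n_partner non-negative event counts (vectorised).
#' @param sample_id optional sample names used in error messages.
#' @return `n_focal / (n_focal + n_partner)`, in `[0, 1]`.
#' @export
mix_fraction <- function(n_focal, n_partner, sample_id = NULL) {
  total <- n_focal + n_partner
  if (any(total < 1)) {
    bad <- which(total < 1)[1]
    id <- if (!is.null(sample_id)) sample_id[bad] else bad
    stop(sprintf("undefined fraction: zero total count for sample '%s'", id))
  }
  n_focal / total
}

#' Spore and loner biases from paired count tables
#'
#' Pairs every `initial` row with the outcome row (spores or loners) of the
#' same `sample_id` and `replicate`, and computes the raw bias
#' `fraction(outcome) - fraction(initial)` — the deviation of the focal
#' population's proportion in the outcome compartment from its proportion in
#' the initial mix. When a label-bias model is supplied, the corrected bias
#' `raw_bias - L(f)` is added, with L evaluated at the measured initial
#' fraction of each chimera (not its nominal target proportion). An optional
#' parametric bootstrap attaches percentile confidence bounds to each raw
#' bias.
#'
#' @param counts count-table data.frame (`sample_id, replicate, compartment,
#'   n_focal, n_partner, ...`).
#' @param outcome which outcome compartment to compare against the initial
#'   mix: `"spores"` (spore bias) or `"loners"` (loner bias).
#' @param label_bias optional [bias_profile] label-bias model.
#' @param ci if `TRUE`, add percentile bootstrap bounds `ci_lo`, `ci_hi`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @param conf confidence level of the bootstrap interval.
#' @return tidy data.frame with columns `sample_id, replicate, compartment,
#'   f, raw_bias` (+ `corrected_bias` and/or `ci_lo, ci_hi`).
#' @export
compute_bias <- function(counts, outcome = c("spores", "loners"),
                         label_bias = NULL, ci = FALSE, n_boot = 1000,
                         seed = NULL, conf = 0.95) {
  outcome <- match.arg(outcome)
  need <- c("sample_id", "replicate", "compartment", "n_focal", "n_partner")
  if (!all(need %in% names(counts)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  ini <- counts[counts$compartment == "initial", , drop = FALSE]
  out <- counts[counts$compartment == outcome, , drop = FALSE]
  if (nrow(ini) == 0) stop("no 'initial' rows in the count table")
  if (nrow(out) == 0) stop(sprintf("no '%s' rows in the count table", outcome))
  key <- function(d) paste(d$sample_id, d$replicate, sep = "\r")
  m <- match(key(out), key(ini))
  if (anyNA(m)) {
    miss <- out[which(is.na(m))[1], ]
    stop(sprintf("pairing error: no initial count for sample '%s' replicate %s",
                 miss$sample_id, miss$replicate))
  }
  ini <- ini[m, , drop = FALSE]
  f_ini <- mix_fraction(ini$n_focal, ini$n_partner, ini$sample_id)
  f_out <- mix_fraction(out$n_focal, out$n_partner, out$sample_id)
  res <- data.frame(
    sample_id = out$sample_id, replicate = out$replicate,
    compartment = outcome, f = f_ini, raw_bias = f_out - f_ini,
    stringsAsFactors = FALSE
  )
  if (!is.null(label_bias)) {
    stopifnot(inherits(label_bias, "bias_profile"))
    res$corrected_bias <- res$raw_bias - predict(label_bias, res$f)
  }
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    n_i <- ini$n_focal + ini$n_partner
    n_o <- out$n_focal + out$n_partner
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    cis <- vapply(seq_len(nrow(res)), function(i) {
      b <- stats::rbinom(n_boot, n_o[i], f_out[i]) / n_o[i] -
        stats::rbinom(n_boot, n_i[i], f_ini[i]) / n_i[i]
      stats::quantile(b, qs, names = FALSE)
    }, numeric(2))
    res$ci_lo <- cis[1, ]
    res$ci_hi <- cis[2, ]
  }
  res
}

#' Subtract a fitted label-bias profile from measured biases
#'
#' @param bias_table output of [compute_bias] (columns `f`, `raw_bias`).
#' @param label_bias a [bias_profile] fitted from isogenic, same-stage
#'   co-cultures of differently labelled populations.
#' @return `bias_table` with a `corrected_bias` column
#'   (`raw_bias - L(f)`, L evaluated at each chimera's measured f).
#' @export
correct_bias <- function(bias_table, label_bias) {
  stopifnot(inherits(label_bias, "bias_profile"),
            all(c("f", "raw_bias") %in% names(bias_table)))
  bias_table$corrected_bias <-
    bias_table$raw_bias - predict(label_bias, bias_table$f)
  bias_table
}

#' Check that two label-swapped profiles mirror each other
#'
#' Swapping the fluorescent labels exchanges focal and partner, so the bias
#' profile measured with swapped labels should satisfy
#' B_AB(f) = -B_BA(1 - f). Checked on a dense frequency grid.
#'
#' @param profile_ab,profile_ba the two fitted [bias_profile]s.
#' @param tolerance maximum admissible absolute deviation.
#' @param n_grid grid resolution.
#' @return logical; attribute `max_deviation` carries the observed maximum of
#'   `|B_AB(f) + B_BA(1 - f)|`.
#' @export
label_swap_check <- function(profile_ab, profile_ba, tolerance, n_grid = 201) {
  stopifnot(inherits(profile_ab, "bias_profile"),
            inherits(profile_ba, "bias_profile"))
  f <- seq(0, 1, length.out = n_grid)
  dev <- max(abs(predict(profile_ab, f) + predict(profile_ba, 1 - f)))
  structure(dev <= tolerance, max_deviation = dev)
}

#' Association between loner bias and spore bias
#'
#' Pearson correlation with its t-distribution p-value, plus a seeded
#' percentile bootstrap confidence interval, for paired (loner bias,
#' spore bias) measurements. A negative correlation is the signature of
#' aggregation-driven biases: populations leaving more loners are
#' under-represented among spores.
#'
#' @param loner_bias,spore_bias paired numeric vectors (>= 3 pairs).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `r`, `p_value`, `ci` (bootstrap percentile), `n`,
#'   `n_boot`.
#' @export
bias_association <- function(loner_bias, spore_bias, n_boot = 1000,
                             seed = NULL, conf = 0.95) {
  stopifnot(length(loner_bias) == length(spore_bias))
  ok <- is.finite(loner_bias) & is.finite(spore_bias)
  x <- loner_bias[ok]; y <- spore_bias[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: zero variance in one coordinate")
  ct <- stats::cor.test(x, y, method = "pearson")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  r_boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx])
  }, numeric(1))
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci = stats::quantile(r_boot, qs, names = FALSE, na.rm = TRUE),
       n = n, n_boot = n_boot)
}
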