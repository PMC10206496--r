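#' Adhesion fraction from a density-based assay
#'
#' Both assays measure a total cell density and a "free" density (cells in
#' the supernatant for the substrate assay; unaggregated singlets/doublets
#' for the cell-cell assay) and report the adhering fraction
#' `(total - free) / total`. The assay protocol's literal wording for the
#' substrate assay would instead report `free / total` ("fraction of
#' adhesive cells" computed from the supernatant); that reading contradicts
#' the cell-cell formula and the observed direction of the substrate-adhesion
#' trend, so the consistent `(total - free) / total` is the default and the
#' literal reading is available behind `literal_supernatant = TRUE`.
#'
#' @param total_density total cell density (> 0), any consistent unit.
#' @param free_density unattached/unaggregated cell density (>= 0, same
#'   unit); must not exceed `total_density`.
#' @param n_counted optional effective number of counted cells, enabling a
#'   Wilson binomial confidence interval on the fraction.
#' @param literal_supernatant report `free / total` instead (see above).
#' @param conf confidence level of the Wilson interval.
#' @return list with `fraction` (in `[0, 1]`) and `ci` (Wilson bounds, or
#'   `NULL` when `n_counted` is missing). The fraction is scale-invariant in
#'   the densities.
#' @export
adhesion_fraction <- function(total_density, free_density, n_counted = NULL,
                              literal_supernatant = FALSE, conf = 0.95) {
  if (total_density <= 0) stop("total_density must be positive")
  if (free_density < 0) stop("free_density must be non-negative")
  if (free_density > total_density)
    stop(sprintf(
      "inconsistent assay: free density (%g) exceeds total density (%g)",
      free_density, total_density))
  frac <- if (literal_supernatant) free_density / total_density
          else (total_density - free_density) / total_density
  ci <- NULL
  if (!is.null(n_counted)) {
    stopifnot(n_counted >= 1)
    ci <- wilson_ci(round(frac * n_counted), n_counted, conf = conf)
  }
  list(fraction = frac, ci = ci)
}

#' Tidy adhesion fractions for an assay table
#'
#' @param assays data.frame with columns `assay` (`substrate` or
#'   `cell_cell`), `stage`, `replicate`, `total_density`, `free_density`,
#'   optionally `n_counted`.
#' @param ... passed on to [adhesion_fraction].
#' @return the input with added columns `fraction`, `ci_lo`, `ci_hi`.
#' @export
adhesion_table <- function(assays, ...) {
  need <- c("assay", "stage", "replicate", "total_density", "free_density")
  if (!all(need %in% names(assays)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  res <- lapply(seq_len(nrow(assays)), function(i) {
    n_counted <- if ("n_counted" %in% names(assays)) assays$n_counted[i]
    af <- adhesion_fraction(assays$total_density[i], assays$free_density[i],
                            n_counted = n_counted, ...)
    c(af$fraction, af$ci %||% c(NA_real_, NA_real_))
  })
  res <- do.call(rbind, res)
  assays$fraction <- res[, 1]
  assays$ci_lo <- res[, 2]
  assays$ci_hi <- res[, 3]
  assays
}

#' Monotonic trend of adhesion fractions across growth stages
#'
#' Tests whether an adhesion fraction changes systematically as a culture
#' ages through the ordered growth phases (default EE < ME < LE < ES):
#' a Spearman rank correlation between stage order and fraction gives the
#' trend statistic, and consecutive stages are compared pairwise via
#' [compare_groups].
#'
#' @param fractions data.frame with columns `stage`, `replicate`,
#'   `fraction` (e.g. one assay's rows from [adhesion_table]).
#' @param stage_order ordered character vector of stages.
#' @param method pairwise comparison method (see [compare_groups]).
#' @return list with `trend` (Spearman rho; 0 when the fractions are
#'   constant), `trend_p`, and `pairwise` (data.frame of consecutive-stage
#'   comparisons; `NULL`, with a warning, when any stage has a single
#'   replicate).
#' @export
stage_trend <- function(fractions, stage_order = c("EE", "ME", "LE", "ES"),
                        method = "student_t") {
  stopifnot(all(c("stage", "replicate", "fraction") %in% names(fractions)))
  fractions <- fractions[fractions$stage %in% stage_order, , drop = FALSE]
  stages <- intersect(stage_order, unique(fractions$stage))
  if (length(stages) < 2) stop("need at least 2 stages")
  rank_stage <- match(fractions$stage, stage_order)

  if (stats::sd(fractions$fraction) == 0) {
    trend <- 0; trend_p <- 1
  } else {
    ct <- suppressWarnings(
      stats::cor.test(rank_stage, fractions$fraction, method = "spearman"))
    trend <- unname(ct$estimate); trend_p <- ct$p.value
  }

  n_rep <- tapply(fractions$replicate, fractions$stage, function(r)
    length(unique(r)))
  pairwise <- NULL
  if (any(n_rep[stages] < 2)) {
    warning("single replicate in at least one stage; pairwise tests skipped")
  } else {
    pairwise <- do.call(rbind, lapply(seq_len(length(stages) - 1), function(i) {
      sub <- fractions[fractions$stage %in% stages[i:(i + 1)], , drop = FALSE]
      cg <- tryCatch(compare_groups(sub$fraction, sub$stage, method = method),
                     error = function(e) list(statistic = NA_real_,
                                              p_value = NA_real_))
      data.frame(stage_a = stages[i], stage_b = stages[i + 1],
                 statistic = cg$statistic, p_value = cg$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(trend = trend, trend_p = trend_p, pairwise = pairwise)
}
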