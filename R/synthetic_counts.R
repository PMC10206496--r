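#' Sample a two-colour count measurement of a binary cell mix
#'
#' Emulates flow-cytometric counting of a GFP/RFP-labelled binary mix: given
#' the true focal frequency `f_true`, the number of focal events is drawn
#' binomially with success probability `clamp(f_true + L(f_true), 0, 1)`,
#' where L is an optional intrinsic label-bias model. Clamping (rather than
#' rejection) mirrors the fact that a physical fraction stays in `[0, 1]`.
#'
#' @param f_true true focal frequency in `[0, 1]`.
#' @param n_events number of counted events (>= 1).
#' @param label_bias optional [bias_profile] giving the label bias L(f);
#'   validated against the admissibility bound |L(f)| <= min(f, 1-f).
#' @param seed integer seed; every call is deterministic given its arguments.
#' @param sample_id,replicate,compartment,stage_focal,stage_partner metadata
#'   copied into the returned row (compartment one of `initial`, `spores`,
#'   `loners`).
#' @return a one-row data.frame in the count-table dialect
#'   (`sample_id, replicate, compartment, n_focal, n_partner, stage_focal,
#'   stage_partner`) plus provenance columns `f_true` and `seed`.
#' @export
sample_mix_counts <- function(f_true, n_events, label_bias = NULL, seed,
                              sample_id = "sim", replicate = 1L,
                              compartment = "initial",
                              stage_focal = NA_character_,
                              stage_partner = NA_character_) {
  if (!is.numeric(f_true) || length(f_true) != 1 || f_true < 0 || f_true > 1)
    stop("f_true must be a single frequency in [0, 1]")
  stopifnot(n_events >= 1)
  compartment <- match.arg(compartment, c("initial", "spores", "loners"))
  p <- f_true
  if (!is.null(label_bias)) {
    validate_label_bias(label_bias)
    p <- clamp(f_true + predict(label_bias, f_true))
  }
  set.seed(seed)
  n_events <- as.integer(n_events)
  n_focal <- stats::rbinom(1, size = n_events, prob = p)
  data.frame(
    sample_id = sample_id, replicate = as.integer(replicate),
    compartment = compartment,
    n_focal = n_focal, n_partner = n_events - n_focal,
    stage_focal = stage_focal, stage_partner = stage_partner,
    f_true = f_true, seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
}
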