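#' Parameters of the go-or-grow chimera simulator
#'
#' Encodes the hypothesised single-cell mechanism linking growth phase to
#' social outcome: cells in the low-motility (putatively dividing) class fail
#' to aggregate more often, so populations enriched in non-migrating cells
#' leave more loners and are under-represented among spores. Aggregation is a
#' per-cell Bernoulli outcome (no spatial signalling); sporulation is a
#' weighted draw among aggregated cells.
#'
#' @param f_init initial focal frequency in `[0, 1]`.
#' @param n_cells total number of cells in the mix (>= 1).
#' @param focal,partner [motility_params] of the two populations (only
#'   `fraction_non_migrating` enters the count-level simulation; the full
#'   parameter set is kept so matched trajectories can be generated).
#' @param loner_prob_non_migrating probability that a non-migrating cell ends
#'   as a loner; must be >= `loner_prob_migrating` (the go-or-grow ordering).
#' @param loner_prob_migrating probability that a migrating cell ends as a
#'   loner.
#' @param sporulation_weight_focal developmental bias multiplier (> 0) for
#'   focal cells when spores are drawn among aggregated cells; 1 = neutral.
#' @param spore_fraction fraction of aggregated cells that become spores
#'   (the remainder die building the stalk).
#' @param seed integer seed.
#' @return an object of class `go_or_grow_params`.
#' @export
go_or_grow_params <- function(f_init, n_cells,
                              focal = motility_params(),
                              partner = motility_params(),
                              loner_prob_non_migrating = 0.8,
                              loner_prob_migrating = 0.1,
                              sporulation_weight_focal = 1,
                              spore_fraction = 0.8,
                              seed = 1L) {
  if (f_init < 0 || f_init > 1) stop("f_init must lie in [0, 1]")
  stopifnot(n_cells >= 1)
  for (q in c(loner_prob_non_migrating, loner_prob_migrating, spore_fraction))
    if (q < 0 || q > 1) stop("probabilities must lie in [0, 1]")
  if (loner_prob_non_migrating < loner_prob_migrating)
    stop("go-or-grow ordering violated: loner_prob_non_migrating must be >= loner_prob_migrating")
  if (sporulation_weight_focal <= 0)
    stop("sporulation_weight_focal must be positive")
  structure(
    list(f_init = f_init, n_cells = as.integer(n_cells),
         focal = focal, partner = partner,
         loner_prob_non_migrating = loner_prob_non_migrating,
         loner_prob_migrating = loner_prob_migrating,
         sporulation_weight_focal = sporulation_weight_focal,
         spore_fraction = spore_fraction, seed = as.integer(seed)),
    class = "go_or_grow_params"
  )
}

#' Closed-form expected compartment fractions of a go-or-grow chimera
#'
#' With q_pop the class-weighted loner probability of a population
#' (q = phi q_nm + (1 - phi) q_m, phi its non-migrating fraction), the
#' expected focal fraction among loners is
#' \deqn{f_L = f q_f / (f q_f + (1 - f) q_p)}
#' and among spores, with aggregated cells reweighted by the sporulation
#' weight w,
#' \deqn{f_S = f (1 - q_f) w / (f (1 - q_f) w + (1 - f)(1 - q_p)).}
#'
#' @param params a [go_or_grow_params] object.
#' @return list with `f_loners`, `f_spores`, `loner_bias` (f_L - f),
#'   `spore_bias` (f_S - f), and the per-population loner probabilities
#'   `q_focal`, `q_partner`.
#' @export
expected_chimera_fractions <- function(params) {
  stopifnot(inherits(params, "go_or_grow_params"))
  f <- params$f_init
  qf <- params$focal$fraction_non_migrating * params$loner_prob_non_migrating +
    (1 - params$focal$fraction_non_migrating) * params$loner_prob_migrating
  qp <- params$partner$fraction_non_migrating * params$loner_prob_non_migrating +
    (1 - params$partner$fraction_non_migrating) * params$loner_prob_migrating
  w <- params$sporulation_weight_focal
  denom_l <- f * qf + (1 - f) * qp
  f_l <- if (denom_l > 0) f * qf / denom_l else NA_real_
  denom_s <- f * (1 - qf) * w + (1 - f) * (1 - qp)
  f_s <- if (denom_s > 0) f * (1 - qf) * w / denom_s else NA_real_
  list(f_loners = f_l, f_spores = f_s,
       loner_bias = f_l - f, spore_bias = f_s - f,
       q_focal = qf, q_partner = qp)
}

#' Simulate one go-or-grow chimera experiment
#'
#' Each cell draws a motility class from its population's mixture weight,
#' then a loner status from the class-specific probability; aggregated
#' (non-loner) cells enter a weighted draw without replacement for a fixed
#' total number of spores (focal cells weighted by the sporulation weight).
#' Compartment counts are conserved exactly: initial = loners + aggregated
#' per population, and spores are a subset of aggregated cells.
#'
#' @param params a [go_or_grow_params] object.
#' @param sample_id,replicate,stage_focal,stage_partner metadata for the
#'   returned count rows.
#' @return an object of class `chimera_sim`: list with
#'   \describe{
#'     \item{counts}{data.frame in the count-table dialect with one row per
#'       compartment (`initial`, `loners`, `spores`).}
#'     \item{detail}{per-population tallies (class and loner/aggregated/spore
#'       breakdown).}
#'     \item{expected}{closed-form expectations from
#'       [expected_chimera_fractions].}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_chimera <- function(params, sample_id = "chimera", replicate = 1L,
                             stage_focal = NA_character_,
                             stage_partner = NA_character_) {
  stopifnot(inherits(params, "go_or_grow_params"))
  set.seed(params$seed)
  n <- params$n_cells
  n_focal <- as.integer(round(params$f_init * n))
  n_partner <- n - n_focal

  draw_pop <- function(n_pop, phi) {
    if (n_pop == 0)
      return(list(nm = 0L, m = 0L, loners = 0L, aggregated = 0L))
    nm <- stats::rbinom(1, n_pop, phi)
    m <- n_pop - nm
    loners <- stats::rbinom(1, nm, params$loner_prob_non_migrating) +
      stats::rbinom(1, m, params$loner_prob_migrating)
    list(nm = nm, m = m, loners = loners, aggregated = n_pop - loners)
  }
  foc <- draw_pop(n_focal, params$focal$fraction_non_migrating)
  par <- draw_pop(n_partner, params$partner$fraction_non_migrating)

  n_agg <- foc$aggregated + par$aggregated
  n_spores <- as.integer(round(params$spore_fraction * n_agg))
  if (n_spores > 0 && n_agg > 0) {
    w <- c(rep(params$sporulation_weight_focal, foc$aggregated),
           rep(1, par$aggregated))
    is_focal <- c(rep(TRUE, foc$aggregated), rep(FALSE, par$aggregated))
    picked <- sample.int(n_agg, n_spores, replace = FALSE, prob = w)
    spores_focal <- sum(is_focal[picked])
  } else {
    spores_focal <- 0L
  }
  spores_partner <- n_spores - spores_focal

  counts <- data.frame(
    sample_id = sample_id, replicate = as.integer(replicate),
    compartment = c("initial", "loners", "spores"),
    n_focal = c(n_focal, foc$loners, spores_focal),
    n_partner = c(n_partner, par$loners, spores_partner),
    stage_focal = stage_focal, stage_partner = stage_partner,
    stringsAsFactors = FALSE
  )
  structure(
    list(counts = counts,
         detail = list(focal = foc, partner = par,
                       n_spores = n_spores, n_aggregated = n_agg),
         expected = expected_chimera_fractions(params),
         params = params),
    class = "chimera_sim"
  )
}

#' Emulate cytometric measurement of a simulated chimera
#'
#' Resamples each compartment of a simulated chimera as a finite two-colour
#' count, emulating the measurement step (flow cytometry for initial mix and
#' spores, image-based counting for loners). The intrinsic fluorescent-label
#' bias is a spore-production effect — isogenic co-cultures at initial
#' frequency f show spore bias L(f) — so it shifts the spores compartment by
#' L evaluated at the chimera's initial frequency; initial and loner counts
#' are label-unbiased.
#'
#' @param sim a `chimera_sim` from [simulate_chimera].
#' @param n_events events counted per compartment.
#' @param label_bias optional [bias_profile] label-bias model L(f).
#' @param seed integer seed.
#' @return a count-table data.frame (one measured row per compartment).
#' @export
measure_chimera <- function(sim, n_events, label_bias = NULL, seed = 1L) {
  stopifnot(inherits(sim, "chimera_sim"))
  ini <- sim$counts[sim$counts$compartment == "initial", ]
  f_init <- ini$n_focal / (ini$n_focal + ini$n_partner)
  shift <- if (is.null(label_bias)) 0 else {
    validate_label_bias(label_bias)
    predict(label_bias, f_init)
  }
  rows <- lapply(seq_len(nrow(sim$counts)), function(i) {
    row <- sim$counts[i, ]
    tot <- row$n_focal + row$n_partner
    f_comp <- if (tot > 0) row$n_focal / tot else NA_real_
    if (row$compartment == "spores") f_comp <- clamp(f_comp + shift)
    sample_mix_counts(f_comp, n_events, label_bias = NULL,
                      seed = child_seed(seed, paste0("measure_", row$compartment)),
                      sample_id = row$sample_id, replicate = row$replicate,
                      compartment = row$compartment,
                      stage_focal = row$stage_focal,
                      stage_partner = row$stage_partner)
  })
  do.call(rbind, rows)
}
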