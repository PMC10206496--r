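#!/usr/bin/env Rscript
# Generate the full synthetic chronochimera experiment: isogenic co-culture
# counts carrying the intrinsic label bias, a go-or-grow chimera frequency
# sweep for three focal growth phases mixed against an EE reference, tracked
# motility samples per phase, and adhesion assay tables.
#
# Study conditions: 9 mixing frequencies x 3 technical replicates, 10^4
# events per cytometric count, ~600 tracked cells per motility sample at
# 30-s frames over 1 h, 3 replicates per adhesion assay and stage.

suppressPackageStartupMessages(library(chronochimera))

seed <- 20230502L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

freqs <- seq(0.1, 0.9, by = 0.1)
n_rep <- 3L
n_events <- 10000L
label_model <- bias_profile(a = 0.12, b = -0.1)   # intrinsic GFP/RFP bias
validate_label_bias(label_model)

# growth-phase-dependent mixture weights: the non-migrating fraction
# decreases as a culture ages through exponential phase, then the loner
# propensity of ES cultures rises again (stationary-phase reversal)
phase_phi <- c(EE = 0.45, ME = 0.20, LE = 0.10, ES = 0.35)

message("-- isogenic EE/EE co-cultures (label-bias calibration)")
cocult <- list(); k <- 0
for (f in freqs) for (r in seq_len(n_rep)) {
  k <- k + 1
  sid <- sprintf("cocult_f%03d", round(100 * f))
  cocult[[length(cocult) + 1]] <- sample_mix_counts(
    f, n_events, seed = child_seed(seed, sprintf("co_i_%d", k)),
    sample_id = sid, replicate = r, compartment = "initial",
    stage_focal = "EE", stage_partner = "EE")
  cocult[[length(cocult) + 1]] <- sample_mix_counts(
    f, n_events, label_bias = label_model,
    seed = child_seed(seed, sprintf("co_s_%d", k)),
    sample_id = sid, replicate = r, compartment = "spores",
    stage_focal = "EE", stage_partner = "EE")
}
write_count_table(do.call(rbind, cocult), file.path(out, "cocult_counts.tsv"))

message("-- go-or-grow chronochimeras (focal ME/LE/ES vs reference EE)")
chim <- list(); k <- 0
for (stage in c("ME", "LE", "ES")) for (f in freqs) for (r in seq_len(n_rep)) {
  k <- k + 1
  pars <- go_or_grow_params(
    f_init = f, n_cells = 10000L,
    focal = motility_params(fraction_non_migrating = phase_phi[[stage]]),
    partner = motility_params(fraction_non_migrating = phase_phi[["EE"]]),
    loner_prob_non_migrating = 0.8, loner_prob_migrating = 0.1,
    sporulation_weight_focal = 1,
    seed = child_seed(seed, sprintf("chim_%d", k)))
  sim <- simulate_chimera(pars,
                          sample_id = sprintf("%s_f%03d", stage, round(100 * f)),
                          replicate = r, stage_focal = stage,
                          stage_partner = "EE")
  chim[[k]] <- measure_chimera(sim, n_events, label_bias = label_model,
                               seed = child_seed(seed, sprintf("meas_%d", k)))
}
write_count_table(do.call(rbind, chim), file.path(out, "chimera_counts.tsv"))

message("-- tracked motility samples per growth phase")
latents <- list()
for (stage in names(phase_phi)) {
  sim <- simulate_trajectories(
    motility_params(fraction_non_migrating = phase_phi[[stage]]),
    n_cells = 600, seed = child_seed(seed, paste0("traj_", stage)),
    cell_prefix = stage)
  write_trajectory_table(sim$tracks,
                         file.path(out, sprintf("trajectories_%s.tsv", stage)))
  latents[[stage]] <- sim$latent
}
utils::write.table(do.call(rbind, c(latents, list(make.row.names = FALSE))),
                   file.path(out, "trajectory_latent_classes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("-- adhesion assay tables")
# substrate adhesion rises and cell-cell adhesion falls as cultures age
substrate_truth <- c(EE = 0.25, ME = 0.40, LE = 0.55, ES = 0.65)
cellcell_truth <- c(EE = 0.75, ME = 0.65, LE = 0.55, ES = 0.45)
set.seed(child_seed(seed, "adhesion"))
adh <- do.call(rbind, lapply(names(substrate_truth), function(stage) {
  do.call(rbind, lapply(1:3, function(r) {
    n_count <- 500
    att_s <- rbinom(1, n_count, substrate_truth[[stage]])
    att_c <- rbinom(1, n_count, cellcell_truth[[stage]])
    data.frame(
      assay = c("substrate", "cell_cell"), stage = stage, replicate = r,
      total_density = 2.5e5,
      free_density = 2.5e5 * (1 - c(att_s, att_c) / n_count),
      n_counted = n_count)
  }))
}))
utils::write.table(adh, file.path(out, "adhesion_assays.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("wrote synthetic experiment under ", out)
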