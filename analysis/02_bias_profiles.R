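#!/usr/bin/env Rscript
# Fit the intrinsic label-bias profile from isogenic co-cultures, correct
# the chimera spore biases, fit per-phase spore-bias profiles, and quantify
# the spore-bias / loner-bias association.

suppressPackageStartupMessages(library(chronochimera))

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE)

cocult <- read_count_table(file.path(data_dir, "cocult_counts.tsv"))
chim <- read_count_table(file.path(data_dir, "chimera_counts.tsv"))

## label-bias calibration ------------------------------------------------------
co_bias <- compute_bias(cocult, "spores")
label_fit <- fit_constrained_cubic(co_bias$f, co_bias$raw_bias,
                                   samples = unique(co_bias$sample_id))
message(sprintf("label bias fit: L(f) = f(1-f)(%.4f %+.4f f), RSS = %.2e",
                label_fit$a, label_fit$b, label_fit$rss))
jsonlite::write_json(list(a = label_fit$a, b = label_fit$b,
                          rss = label_fit$rss, n_points = label_fit$n_points),
                     file.path(out, "label_bias_profile.json"),
                     auto_unbox = TRUE, digits = NA)

## corrected spore and loner biases -------------------------------------------
spore_tbl <- compute_bias(chim, "spores", label_bias = label_fit, ci = TRUE,
                          n_boot = 1000, seed = 1)
loner_tbl <- compute_bias(chim, "loners", ci = TRUE, n_boot = 1000, seed = 2)
loner_tbl$corrected_bias <- NA_real_   # label correction is calibrated on spores
loner_tbl <- loner_tbl[names(spore_tbl)]
spore_tbl$stage <- sub("_f[0-9]+$", "", spore_tbl$sample_id)
loner_tbl$stage <- sub("_f[0-9]+$", "", loner_tbl$sample_id)
utils::write.table(rbind(spore_tbl[names(spore_tbl) != "stage"],
                         loner_tbl[names(loner_tbl) != "stage"]),
                   file.path(out, "bias_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## per-phase corrected spore-bias profiles -------------------------------------
profiles <- lapply(split(spore_tbl, spore_tbl$stage), function(d)
  fit_constrained_cubic(d$f, d$corrected_bias, samples = unique(d$sample_id)))
for (stage in names(profiles)) {
  p <- profiles[[stage]]
  message(sprintf("%s vs EE: B(f) = f(1-f)(%.4f %+.4f f)  [n=%d, RSS=%.2e]",
                  stage, p$a, p$b, p$n_points, p$rss))
}
jsonlite::write_json(
  lapply(profiles, function(p) list(a = p$a, b = p$b, rss = p$rss,
                                    n_points = p$n_points)),
  file.path(out, "spore_bias_profiles.json"), auto_unbox = TRUE, digits = NA)

## spore bias vs loner bias ----------------------------------------------------
key <- function(d) paste(d$sample_id, d$replicate)
m <- match(key(spore_tbl), key(loner_tbl))
pairs <- data.frame(spore = spore_tbl$corrected_bias,
                    loner = loner_tbl$raw_bias[m])
assoc <- bias_association(pairs$loner, pairs$spore, n_boot = 1000, seed = 3)
message(sprintf(
  "loner bias vs spore bias: Pearson r = %.3f (p = %.2g, 95%% CI %.3f..%.3f, n = %d)",
  assoc$r, assoc$p_value, assoc$ci[1], assoc$ci[2], assoc$n))
jsonlite::write_json(list(r = assoc$r, p_value = assoc$p_value,
                          ci = assoc$ci, n = assoc$n),
                     file.path(out, "bias_association.json"),
                     auto_unbox = TRUE, digits = NA)
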