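#!/usr/bin/env Rscript
# Adhesion fractions with binomial intervals and their trends across the
# growth-phase order EE < ME < LE < ES.

suppressPackageStartupMessages(library(chronochimera))

data_dir <- "results/data"
out <- "results"

assays <- utils::read.delim(file.path(data_dir, "adhesion_assays.tsv"))
tidy <- adhesion_table(assays)
utils::write.table(tidy, file.path(out, "adhesion_fractions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

trends <- list()
for (assay in c("substrate", "cell_cell")) {
  sub <- tidy[tidy$assay == assay, ]
  tr <- stage_trend(sub)
  dir <- if (tr$trend > 0) "increases" else "decreases"
  message(sprintf(
    "%s adhesion %s with culture age: Spearman rho = %.3f (p = %.3g)",
    assay, dir, tr$trend, tr$trend_p))
  for (i in seq_len(nrow(tr$pairwise)))
    message(sprintf("  %s vs %s: p = %.3g", tr$pairwise$stage_a[i],
                    tr$pairwise$stage_b[i], tr$pairwise$p_value[i]))
  trends[[assay]] <- list(trend = tr$trend, trend_p = tr$trend_p,
                          pairwise = tr$pairwise)
}
jsonlite::write_json(trends, file.path(out, "adhesion_trends.json"),
                     auto_unbox = TRUE, digits = NA)
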