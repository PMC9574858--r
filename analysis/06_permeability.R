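#!/usr/bin/env Rscript
# Permeability surrogates and the descriptor-permeability ranking. The
# published potency and transport values for the three-compound series are
# inputs: cellular and biochemical CRBN IC50s (cell/bio ratio = potency
# drop on crossing the membrane) and Caco-2 passive permeabilities. The
# ranking ties low ensemble polarity to high permeability.

library(protacfold)
suppressMessages(library(jsonlite))

out_dir <- "results"
# published assay values for the compound series: IC50s in uM, P_passive
# in nm/s (geometric mean of Papp AB/BA)
assays <- data.frame(
  compound_id = c("protac1", "protac2", "protac3"),
  ic50_cell = c(0.924, 16.9, 18.0),
  ic50_bio = c(0.244, 1.41, 0.667),
  p_passive = c(30, 11, 6))

r <- cell_bio_ratio(assays$ic50_cell, assays$ic50_bio)
assays$cell_bio_ratio <- r$ratio
assays$ratio_display <- r$display
cat("cell/bio potency ratios:",
    paste(sprintf("%s %.2f (displays %d)", assays$compound_id, r$ratio,
                  r$display), collapse = "; "), "\n")

means <- read_json(file.path(out_dir, "descriptor_means.json"),
                   simplifyVector = TRUE)
tabs <- lapply(means, function(m) {
  structure(list(table = NULL, means = unlist(m)), class = "descriptor_table")
})
rec <- data.frame(compound_id = assays$compound_id,
                  permeability = assays$p_passive)
rr <- rank_report(rec, tabs)
print(rr)
utils::write.csv(cbind(rr$table, ratio_display = assays$ratio_display),
                 file.path(out_dir, "permeability_ranking.csv"),
                 row.names = FALSE)
cat(sprintf("low-polarity/high-permeability concordance: %.2f; %d discordant pair(s)\n",
            rr$concordance, length(rr$discordant_pairs)))
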