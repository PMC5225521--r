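#!/usr/bin/env Rscript
# Stage 7: assemble the run summary — DEGs with their TSS openness state,
# shared/unique DHS fractions between conditions, the feature
# distribution, and the enrichment and co-localization tables.

source("analysis/00_config.R")
out <- stage_dir("07_report")

degs <- read_stage_tsv("results/02_expression/degs.tsv")
tss <- read_stage_tsv("results/04_tss_openness/tss_openness.tsv")
merged <- read_stage_tsv("results/03_chromatin/merged_dhs.tsv")
surv <- read_stage_tsv("results/06_survival/survival.tsv")

if (nrow(degs)) {
  idx <- match(degs$gene_id, tss$gene_id)
  degs$tss_state_treated <- tss$state_treated[idx]
  degs$tss_state_vehicle <- tss$state_vehicle[idx]
  sidx <- match(degs$gene_id, surv$gene_id)
  degs$logrank_p_adjusted <- surv$p_adjusted[sidx]
}
write_stage_tsv(degs, file.path(out, "deg_summary.tsv"), "report", hash)

shared <- merged$from_treated > 0 & merged$from_vehicle > 0
sharing <- data.frame(n_merged = nrow(merged),
                      shared_fraction = mean(shared),
                      unique_treated_fraction =
                        mean(merged$from_treated > 0 & !shared),
                      unique_vehicle_fraction =
                        mean(merged$from_vehicle > 0 & !shared))
write_stage_tsv(sharing, file.path(out, "dhs_sharing.tsv"), "report", hash)

cat("== run summary ==\n")
cat(sprintf("DEGs: %d (%d with open vehicle TSS, %d prognostic at FDR 0.05)\n",
            nrow(degs),
            if (nrow(degs)) sum(degs$tss_state_vehicle == "open") else 0L,
            if (nrow(degs)) sum(degs$logrank_p_adjusted < 0.05) else 0L))
cat(sprintf("merged DHSs: %d, %.1f%% shared between conditions\n",
            sharing$n_merged, 100 * sharing$shared_fraction))
cat("tables under results/07_report\n")
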