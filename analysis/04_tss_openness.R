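#!/usr/bin/env Rscript
# Stage 4: chromatin openness of transcription start sites. Every
# transcript TSS is extended 1000 bp both ways; per-gene openness is the
# expression-weighted sum of window coverages (with the stated fallbacks
# for unexpressed genes), and genes in the lowest coverage quintile are
# classified closed.

source("analysis/00_config.R")
out <- stage_dir("04_tss_openness")

ann <- read_annotation()
merged <- read_stage_tsv("results/03_chromatin/merged_dhs.tsv")
means <- read_stage_tsv("results/02_expression/normalized_means.tsv")

win <- tss_windows(ann, cfg$tss_extension)
cov_t <- setNames(count_window_reads(win, merged, "reads_treated"),
                  win$transcript_id)
cov_v <- setNames(count_window_reads(win, merged, "reads_vehicle"),
                  win$transcript_id)

# per-transcript expression shares (simulated once per run, seed-stable)
tx <- ann$transcripts
set.seed(substream_seed(cfg$seed, "pipeline"))
share <- runif(nrow(tx), 0.2, 1)
expr_tx <- function(gene_means) {
  g <- setNames(gene_means, means$gene_id)[tx$gene_id]
  s <- unsplit(lapply(split(share, tx$gene_id), function(x) x / sum(x)),
               tx$gene_id)
  setNames(g * s, tx$transcript_id)
}
e_t <- expr_tx(means$mean_treated)
e_v <- expr_tx(means$mean_vehicle)

op_t <- tss_openness(ann, cov_t, e_t, e_v)
op_v <- tss_openness(ann, cov_v, e_v, e_t)
res <- data.frame(gene_id = op_t$gene_id,
                  coverage_treated = op_t$weighted_coverage,
                  coverage_vehicle = op_v$weighted_coverage,
                  state_treated = classify_tss(op_t$weighted_coverage),
                  state_vehicle = classify_tss(op_v$weighted_coverage))
write_stage_tsv(res, file.path(out, "tss_openness.tsv"), "tss_openness", hash)

degs <- read_stage_tsv("results/02_expression/degs.tsv")
deg_states <- res$state_vehicle[match(degs$gene_id, res$gene_id)]
cat(sprintf("TSS openness: %.1f%% open (vehicle), %.1f%% open (treated)\n",
            100 * mean(res$state_vehicle == "open"),
            100 * mean(res$state_treated == "open")))
if (nrow(degs))
  cat(sprintf("of %d DEGs, %d already open in vehicle\n",
              nrow(degs), sum(deg_states == "open")))
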