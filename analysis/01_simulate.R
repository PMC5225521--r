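#!/usr/bin/env Rscript
# Stage 1: generate every input of the analysis with recorded ground truth:
# a gene annotation, replicated vehicle/treated RNA-seq counts with planted
# fold changes, a unified DHS peak set with planted differential openness,
# promoter sequences with planted motif occurrences, and the truth file.

source("analysis/00_config.R")
dir.create(inputs_dir, showWarnings = FALSE, recursive = TRUE)

ann <- generate_annotation(cfg$n_genes, cfg$transcripts_per_gene,
                           cfg$chrom_length, seed = cfg$seed,
                           promoter_length = cfg$promoter_length)
cnt <- generate_counts(ann, cfg$n_de, cfg$log2_fold, cfg$dispersion,
                       depth = cfg$depth, seed = cfg$seed,
                       n_reps = cfg$n_reps)
dhs <- generate_dhs(ann, cfg$n_peaks, cfg$n_diff, cfg$openness_fold,
                    seed = cfg$seed)
truth_up <- cnt$truth$de_genes$gene_id[cnt$truth$de_genes$log2_fold > 0]
prom <- generate_promoters(ann, cfg$motif_consensus, cfg$planted_rate_fg,
                           cfg$planted_rate_bg, gc = cfg$gc,
                           seed = cfg$seed, fg_genes = truth_up,
                           motif_id = cfg$motif_consensus)

write_annotation_gtf(ann, file.path(inputs_dir, "annotation.gtf"))
write_counts_tsv(cbind(cnt$vehicle, cnt$treated),
                 file.path(inputs_dir, "counts.tsv"))
write_peaks_bed(dhs$peaks, file.path(inputs_dir, "dhs_peaks.bed"))
write_fasta(prom$sequences, file.path(inputs_dir, "promoters.fa"))
write_truth_json(list(de_genes = cnt$truth$de_genes,
                      diff_dhs = dhs$truth$diff_dhs,
                      motif_positions = prom$truth$motif_positions),
                 file.path(inputs_dir, "truth.json"))

cat(sprintf("simulated %d genes (%d transcripts), %d planted DEGs,\n",
            nrow(ann$genes), nrow(ann$transcripts), cfg$n_de))
cat(sprintf("%d DHS peaks (%d with %.1fx planted openness), %d promoters\n",
            cfg$n_peaks, cfg$n_diff, cfg$openness_fold, nrow(ann$genes)))
cat("inputs written to", inputs_dir, "\n")
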