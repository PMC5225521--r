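#!/usr/bin/env Rscript
# Stage 3: DHS processing — per-condition read-support filtering (>= 20
# reads in sample and input control), 100 bp adjacency merging, genomic
# feature annotation (promoter > 5'UTR > 3'UTR > exon > intron >
# intergenic), deltaDHS scoring over the unified set, and selection of
# differential sites at |deltaDHS| >= 0.20.

source("analysis/00_config.R")
out <- stage_dir("03_chromatin")

ann <- read_annotation()
pk <- read_peaks_bed(file.path(inputs_dir, "dhs_peaks.bed"))
kept_t <- pk$peak_id %in% filter_dhs(pk, cfg$min_reads,
                                     sample_col = "reads_treated",
                                     input_col = "input_treated")$peak_id
kept_v <- pk$peak_id %in% filter_dhs(pk, cfg$min_reads,
                                     sample_col = "reads_vehicle",
                                     input_col = "input_vehicle")$peak_id
pk$from_treated <- as.integer(kept_t)
pk$from_vehicle <- as.integer(kept_v)
pk <- pk[kept_t | kept_v, , drop = FALSE]

merged <- merge_adjacent(pk, cfg$merge_gap,
                         count_cols = c("reads_treated", "reads_vehicle",
                                        "input_treated", "input_vehicle",
                                        "from_treated", "from_vehicle"))
merged$feature <- annotate_dhs(merged, ann)
merged$delta_dhs <- delta_dhs(merged$reads_treated, merged$reads_vehicle)
merged$selected <- select_differential(merged$delta_dhs, cfg$delta_threshold)

write_stage_tsv(merged, file.path(out, "merged_dhs.tsv"), "chromatin", hash)
dist <- as.data.frame(table(feature = merged$feature))
names(dist) <- c("feature", "n_peaks")
write_stage_tsv(dist, file.path(out, "annotation_distribution.tsv"),
                "chromatin", hash)

shared <- merged$from_treated > 0 & merged$from_vehicle > 0
cat(sprintf("%d peaks passed filtering in either condition; %d after merging\n",
            nrow(pk), nrow(merged)))
cat(sprintf("shared between conditions: %.1f%%; feature mix: %s\n",
            100 * mean(shared),
            paste(dist$feature, dist$n_peaks, sep = "=", collapse = " ")))
cat(sprintf("%d DHSs selected at deltaDHS >= %.2f\n",
            sum(merged$selected), cfg$delta_threshold))
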