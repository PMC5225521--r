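#!/usr/bin/env Rscript
# Stage 2: median-of-ratios normalization of the simulated counts, then
# dual-threshold DEG calling (|log2 ratio| >= 0.75 and normalized count
# difference >= 50 between condition means).

source("analysis/00_config.R")
out <- stage_dir("02_expression")

counts <- read_counts_tsv(file.path(inputs_dir, "counts.tsv"))
sf <- compute_size_factors(counts)
norm <- normalize_counts(counts, sf)
veh_cols <- grep("^vehicle", colnames(norm), value = TRUE)
trt_cols <- grep("^treated", colnames(norm), value = TRUE)
mean_veh <- rowMeans(norm[, veh_cols, drop = FALSE])
mean_trt <- rowMeans(norm[, trt_cols, drop = FALSE])
degs <- call_degs(mean_veh, mean_trt, cfg$log2_min, cfg$diff_min)

write_stage_tsv(data.frame(sample = names(sf$s), size_factor = unname(sf$s)),
                file.path(out, "size_factors.tsv"), "expression", hash)
write_stage_tsv(degs, file.path(out, "degs.tsv"), "expression", hash)
means <- data.frame(gene_id = rownames(norm), mean_vehicle = mean_veh,
                    mean_treated = mean_trt)
write_stage_tsv(means, file.path(out, "normalized_means.tsv"),
                "expression", hash)

truth <- jsonlite::read_json(file.path(inputs_dir, "truth.json"),
                             simplifyVector = TRUE)
planted <- truth$de_genes$gene_id
cat(sprintf("size factors span %.3f-%.3f\n", min(sf$s), max(sf$s)))
cat(sprintf("%d DEGs called (%d up, %d down); %d/%d planted recovered, %d false\n",
            nrow(degs), sum(degs$direction == "up"),
            sum(degs$direction == "down"),
            sum(planted %in% degs$gene_id), length(planted),
            sum(!degs$gene_id %in% planted)))
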