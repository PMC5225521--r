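# Shared configuration for the analysis drivers (sourced by 01..07).
# One global seed drives every generator substream; stage thresholds are
# the workflow defaults (log2 ratio 0.75, count diff 50, >= 20 reads per
# retained DHS, 100 bp merge gap, +/-1000 bp TSS windows, 2000 bp
# promoters, deltaDHS >= 0.20, motif p <= 0.001, 200 bp co-localization).

library(dhsreg)

cfg <- pipeline_config(seed = 1)
inputs_dir <- "results/01_inputs"
stage_dir <- function(name) {
  dir.create(file.path("results", name), showWarnings = FALSE,
             recursive = TRUE)
  file.path("results", name)
}
hash <- config_hash(cfg)

read_annotation <- function() {
  read_annotation_gtf(file.path(inputs_dir, "annotation.gtf"),
                      chrom_length = cfg$chrom_length,
                      promoter_length = cfg$promoter_length)
}
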