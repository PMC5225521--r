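#' Run the integrated analysis end-to-end on synthetic data
#'
#' Executes the full workflow: input simulation, count normalization and
#' DEG calling, DHS filtering/merging/annotation and deltaDHS scoring, TSS
#' openness classification, promoter-DHS motif scanning, enrichment and
#' co-localization, and the median-split survival screen. Every stage
#' writes a self-describing TSV (header carrying the configuration hash)
#' under `outdir`, plus a deterministic run log; reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param blacklist optional blacklist region data frame (`chrom`,
#'   `start`, `end`).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, outdir, blacklist = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("dhsreg run config_hash=%s seed=%d", hash,
                         as.integer(config$seed)),
                 sprintf("config: %s", paste(names(config), unlist(config),
                                             sep = "=", collapse = " ")))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  ## -- simulate ----------------------------------------------------------
  out$annotation <- stage("simulate", generate_annotation(
    config$n_genes, config$transcripts_per_gene, config$chrom_length,
    seed = config$seed, promoter_length = config$promoter_length))
  cnt <- stage("simulate", generate_counts(
    out$annotation, config$n_de, config$log2_fold, config$dispersion,
    depth = config$depth, seed = config$seed, n_reps = config$n_reps))
  dhs <- stage("simulate", generate_dhs(
    out$annotation, config$n_peaks, config$n_diff, config$openness_fold,
    seed = config$seed))
  truth_up <- cnt$truth$de_genes$gene_id[cnt$truth$de_genes$log2_fold > 0]
  prom <- stage("simulate", generate_promoters(
    out$annotation, config$motif_consensus, config$planted_rate_fg,
    config$planted_rate_bg, gc = config$gc, seed = config$seed,
    fg_genes = truth_up, motif_id = config$motif_consensus))
  out$counts <- cnt; out$dhs <- dhs; out$promoters <- prom
  if (nrow(out$annotation$genes)) {
    write_annotation_gtf(out$annotation, file.path(outdir, "annotation.gtf"))
    write_fasta(prom$sequences, file.path(outdir, "promoters.fa"))
  }
  write_counts_tsv(cbind(cnt$vehicle, cnt$treated),
                   file.path(outdir, "counts.tsv"))
  write_peaks_bed(dhs$peaks, file.path(outdir, "dhs_peaks.bed"))
  write_truth_json(list(de_genes = cnt$truth$de_genes,
                        diff_dhs = dhs$truth$diff_dhs,
                        motif_positions = prom$truth$motif_positions),
                   file.path(outdir, "truth.json"))
  note("simulate: %d genes, %d peaks, %d planted DEGs, %d planted diff DHSs",
       nrow(out$annotation$genes), nrow(dhs$peaks),
       nrow(cnt$truth$de_genes), nrow(dhs$truth$diff_dhs))

  ## -- expression --------------------------------------------------------
  out$expression <- stage("expression", {
    counts <- cbind(cnt$vehicle, cnt$treated)
    sf <- compute_size_factors(counts)
    norm <- normalize_counts(counts, sf)
    mean_veh <- rowMeans(norm[, colnames(cnt$vehicle), drop = FALSE])
    mean_trt <- rowMeans(norm[, colnames(cnt$treated), drop = FALSE])
    degs <- call_degs(mean_veh, mean_trt, config$log2_min, config$diff_min)
    list(size_factors = sf, normalized = norm, mean_vehicle = mean_veh,
         mean_treated = mean_trt, degs = degs)
  })
  write_stage_tsv(out$expression$degs, file.path(outdir, "degs.tsv"),
                  "expression", hash)
  write_stage_tsv(data.frame(sample = names(out$expression$size_factors$s),
                             size_factor = unname(out$expression$size_factors$s)),
                  file.path(outdir, "size_factors.tsv"), "expression", hash)
  note("expression: %d DEGs (%d up) of %d genes",
       nrow(out$expression$degs),
       sum(out$expression$degs$direction == "up"),
       nrow(out$annotation$genes))

  ## -- chromatin ---------------------------------------------------------
  out$chromatin <- stage("chromatin", {
    pk <- dhs$peaks
    kept_t <- pk$peak_id %in% filter_dhs(pk, config$min_reads, blacklist,
                                         "reads_treated", "input_treated")$peak_id
    kept_v <- pk$peak_id %in% filter_dhs(pk, config$min_reads, blacklist,
                                         "reads_vehicle", "input_vehicle")$peak_id
    pk$from_treated <- as.integer(kept_t)
    pk$from_vehicle <- as.integer(kept_v)
    pk <- pk[kept_t | kept_v, , drop = FALSE]
    merged <- merge_adjacent(pk, config$merge_gap,
                             count_cols = c("reads_treated", "reads_vehicle",
                                            "input_treated", "input_vehicle",
                                            "from_treated", "from_vehicle"))
    merged$feature <- annotate_dhs(merged, out$annotation)
    merged$delta_dhs <- delta_dhs(merged$reads_treated, merged$reads_vehicle)
    merged$selected <- select_differential(merged$delta_dhs,
                                           config$delta_threshold)
    merged
  })
  write_stage_tsv(out$chromatin, file.path(outdir, "merged_dhs.tsv"),
                  "chromatin", hash)
  ann_dist <- as.data.frame(table(feature = out$chromatin$feature),
                            stringsAsFactors = FALSE)
  names(ann_dist) <- c("feature", "n_peaks")
  write_stage_tsv(ann_dist, file.path(outdir, "annotation_distribution.tsv"),
                  "chromatin", hash)
  note("chromatin: %d merged DHSs, %d selected at deltaDHS >= %.2f",
       nrow(out$chromatin), sum(out$chromatin$selected),
       config$delta_threshold)

  ## -- tss openness ------------------------------------------------------
  out$tss <- stage("tss_openness", {
    win <- tss_windows(out$annotation, config$tss_extension)
    cov_t <- setNames(count_window_reads(win, out$chromatin, "reads_treated"),
                      win$transcript_id)
    cov_v <- setNames(count_window_reads(win, out$chromatin, "reads_vehicle"),
                      win$transcript_id)
    tx <- out$annotation$transcripts
    set.seed(substream_seed(config$seed, "pipeline"))
    share <- runif(nrow(tx), 0.2, 1)
    expr_tx <- function(gene_means) {
      g <- gene_means[tx$gene_id]
      s <- unsplit(lapply(split(share, tx$gene_id), function(x) x / sum(x)),
                   tx$gene_id)
      setNames(g * s, tx$transcript_id)
    }
    e_t <- expr_tx(out$expression$mean_treated)
    e_v <- expr_tx(out$expression$mean_vehicle)
    op_t <- tss_openness(out$annotation, cov_t, e_t, e_v)
    op_v <- tss_openness(out$annotation, cov_v, e_v, e_t)
    data.frame(gene_id = op_t$gene_id,
               coverage_treated = op_t$weighted_coverage,
               coverage_vehicle = op_v$weighted_coverage,
               state_treated = classify_tss(op_t$weighted_coverage),
               state_vehicle = classify_tss(op_v$weighted_coverage),
               stringsAsFactors = FALSE)
  })
  write_stage_tsv(out$tss, file.path(outdir, "tss_openness.tsv"),
                  "tss_openness", hash)
  note("tss_openness: %d genes, %.1f%% open in vehicle",
       nrow(out$tss), 100 * mean(out$tss$state_vehicle == "open"))

  ## -- motif scan + enrichment + co-localization -------------------------
  out$enrichment <- stage("enrichment", {
    up_called <- out$expression$degs$gene_id[
      out$expression$degs$direction == "up"]
    frag_all <- promoter_dhs_fragments(out$annotation, out$chromatin,
                                       prom$sequences)
    if (!nrow(frag_all$assignment))
      stop("no promoter-overlapping DHS in the merged set")
    split <- build_background(frag_all$assignment, up_called)
    fg_peaks <- out$chromatin[out$chromatin$peak_id %in%
                              split$foreground$peak_id, , drop = FALSE]
    bg_peaks <- out$chromatin[out$chromatin$peak_id %in%
                              split$background$peak_id, , drop = FALSE]
    fg_frag <- promoter_dhs_fragments(out$annotation, fg_peaks,
                                      prom$sequences)$fragments
    fg_frag <- fg_frag[fg_frag$gene_id %in% up_called, , drop = FALSE]
    bg_frag <- promoter_dhs_fragments(out$annotation, bg_peaks,
                                      prom$sequences)$fragments
    fg_seqs <- setNames(fg_frag$sequence, fg_frag$fragment_id)
    bg_seqs <- setNames(bg_frag$sequence, bg_frag$fragment_id)
    pwm <- build_pwm(consensus_wpcm(config$motif_consensus),
                     q = background_frequencies(c(fg_seqs, bg_seqs)))
    enr <- tfbs_enrichment(fg_seqs, bg_seqs, pwm, p = config$motif_p)
    thr <- score_threshold(pwm, p = config$motif_p)
    hits <- scan_pwm(fg_seqs, pwm, thr)
    sbe <- find_consensus(fg_seqs, sbe_patterns())
    lens <- setNames(nchar(fg_seqs), names(fg_seqs))
    coloc <- do.call(rbind, lapply(sbe_patterns(), function(pat) {
      ct <- colocalization_test(hits, sbe[sbe$pattern == pat, , drop = FALSE],
                                lens, config$coloc_window)
      data.frame(sbe_pattern = pat, ct, stringsAsFactors = FALSE)
    }))
    list(table = enr, hits = hits, sbe = sbe, coloc = coloc,
         foreground = fg_frag, background = bg_frag)
  })
  write_stage_tsv(out$enrichment$table, file.path(outdir, "enrichment.tsv"),
                  "enrichment", hash)
  write_stage_tsv(out$enrichment$coloc,
                  file.path(outdir, "colocalization.tsv"), "enrichment", hash)
  note("enrichment: %d fg / %d bg fragments, ratio %s",
       nrow(out$enrichment$foreground), nrow(out$enrichment$background),
       paste(round(out$enrichment$table$ratio, 3), collapse = ","))

  ## -- survival ----------------------------------------------------------
  out$survival <- stage("survival", {
    degs <- out$expression$degs$gene_id
    if (!length(degs)) {
      data.frame(gene_id = character(), chisq = numeric(), p = numeric(),
                 p_adjusted = numeric(), worse_group = character(),
                 stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_along(degs), function(i) {
        cohort <- generate_survival(config$n_patients, config$hazard_ratio,
                                    config$censor_rate,
                                    seed = config$seed + 131 * i)
        grp <- median_split(cohort$expression)
        lr <- logrank_test(cohort$time, cohort$event, grp)
        data.frame(gene_id = degs[i], chisq = lr$chisq, p = lr$p,
                   worse_group = if (lr$observed > lr$expected) "low"
                                 else "high",
                   stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, rows)
      d$p_adjusted <- bh_adjust(d$p)
      d[, c("gene_id", "chisq", "p", "p_adjusted", "worse_group")]
    }
  })
  write_stage_tsv(out$survival, file.path(outdir, "survival.tsv"),
                  "survival", hash)
  note("survival: %d DEGs screened, %d with adjusted p < 0.05",
       nrow(out$survival), sum(out$survival$p_adjusted < 0.05))

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(out)
}

#' Summarize a finished pipeline run
#'
#' Reads the stage outputs back from `outdir` and assembles the report
#' tables: the DEG list with per-DEG TSS openness states, the
#' shared/unique DHS fractions between conditions (computed on the merged
#' unified peak set: a merged DHS is shared iff it contains at least one
#' contributing peak from each condition), the genomic-feature
#' distribution of the DHSs, and the enrichment table. Sections whose
#' stage output is missing are marked absent (`NULL`).
#'
#' @param outdir directory written by [run_pipeline()].
#' @return list with `deg_summary`, `dhs_sharing`,
#'   `annotation_distribution`, `enrichment`, and `absent` (names of
#'   missing sections).
#' @export
make_report <- function(outdir) {
  grab <- function(file) {
    p <- file.path(outdir, file)
    if (file.exists(p)) read_stage_tsv(p) else NULL
  }
  degs <- grab("degs.tsv"); tss <- grab("tss_openness.tsv")
  merged <- grab("merged_dhs.tsv")
  deg_summary <- if (!is.null(degs)) {
    if (nrow(degs) && !is.null(tss)) {
      idx <- match(degs$gene_id, tss$gene_id)
      degs$tss_state_treated <- tss$state_treated[idx]
      degs$tss_state_vehicle <- tss$state_vehicle[idx]
    }
    degs
  }
  dhs_sharing <- if (!is.null(merged) && nrow(merged)) {
    shared <- merged$from_treated > 0 & merged$from_vehicle > 0
    data.frame(
      n_merged = nrow(merged),
      shared_fraction = mean(shared),
      unique_treated_fraction = mean(merged$from_treated > 0 & !shared),
      unique_vehicle_fraction = mean(merged$from_vehicle > 0 & !shared))
  }
  sections <- list(deg_summary = deg_summary, dhs_sharing = dhs_sharing,
                   annotation_distribution = grab("annotation_distribution.tsv"),
                   enrichment = grab("enrichment.tsv"))
  report <- sections
  report$absent <- names(sections)[vapply(sections, is.null, logical(1))]
  for (f in c("deg_summary", "dhs_sharing")) {
    if (!is.null(report[[f]]))
      write_stage_tsv(report[[f]], file.path(outdir, paste0("report_", f, ".tsv")),
                      "report", "report")
  }
  report
}
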