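#' Pipeline configuration
#'
#' Collects every stage threshold of the workflow (with the standard
#' defaults: log2 ratio 0.75, count difference 50, minimal peak reads 20,
#' merge gap 100 bp, TSS extension 1000 bp, promoter length 2000 bp,
#' deltaDHS threshold 0.20, motif match p 0.001, co-localization window
#' 200 bp) together with the synthetic-data scale parameters and the
#' global seed. Unknown keys are rejected by R's argument matching;
#' thresholds must be positive.
#'
#' @param log2_min,diff_min DEG thresholds (log2 ratio, normalized-count
#'   difference).
#' @param min_reads minimal sample and input reads per retained DHS.
#' @param merge_gap maximal gap in bp for DHS merging.
#' @param tss_extension TSS half-window in bp.
#' @param promoter_length proximal promoter length in bp.
#' @param delta_threshold deltaDHS selection threshold.
#' @param motif_p PWM match tail probability.
#' @param coloc_window co-localization distance in bp.
#' @param seed global seed expanded into generator substreams.
#' @param n_genes,transcripts_per_gene,chrom_length annotation scale.
#' @param n_de,log2_fold,dispersion,depth,n_reps count-simulation scale.
#' @param n_peaks,n_diff,openness_fold DHS-simulation scale.
#' @param motif_consensus,planted_rate_fg,planted_rate_bg,gc promoter
#'   simulation: planted consensus and insertion rates.
#' @param n_patients,hazard_ratio,censor_rate survival-simulation scale.
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(log2_min = 0.75, diff_min = 50, min_reads = 20,
                            merge_gap = 100, tss_extension = 1000,
                            promoter_length = 2000, delta_threshold = 0.20,
                            motif_p = 0.001, coloc_window = 200, seed = 1L,
                            n_genes = 60, transcripts_per_gene = 2,
                            chrom_length = 2e6,
                            n_de = 8, log2_fold = 2, dispersion = 0.05,
                            depth = 2e5, n_reps = 3,
                            n_peaks = 300, n_diff = 30, openness_fold = 4,
                            motif_consensus = "GGCGCC",
                            planted_rate_fg = 3, planted_rate_bg = 0.5,
                            gc = 0.41,
                            n_patients = 100, hazard_ratio = 2.5,
                            censor_rate = 0.2) {
  cfg <- as.list(environment())
  for (nm in c("log2_min", "diff_min", "min_reads", "merge_gap",
               "tss_extension", "promoter_length", "delta_threshold",
               "motif_p", "coloc_window"))
    assert_scalar_number(cfg[[nm]], nm, min = 0, strict_min = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Deterministic hash of a configuration
#'
#' A short hexadecimal digest of the deparsed configuration, recorded in
#' every stage output header so outputs are traceable to the run.
#'
#' @param config a `pipeline_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  codes <- utf8ToInt(txt)
  h <- 0
  for (x in codes) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a WPCM from a consensus string
#'
#' Utility for tests and synthetic runs: each position gives weight
#' `W * match_weight` to the consensus base and spreads the remainder over
#' the other bases (an `n` position is uniform).
#'
#' @param consensus A/C/G/T/n string.
#' @param W total weight per position.
#' @param match_weight fraction of W on the consensus base.
#' @param motif_id motif identifier (defaults to the consensus).
#' @return a `wpcm`.
#' @export
consensus_wpcm <- function(consensus, W = 20, match_weight = 0.85,
                           motif_id = consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T", "N")))
  counts <- vapply(bases, function(b) {
    if (b == "N") rep(W / 4, 4)
    else {
      x <- rep(W * (1 - match_weight) / 3, 4)
      x[match(b, c("A", "C", "G", "T"))] <- W * match_weight
      x
    }
  }, numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  new_wpcm(motif_id, counts)
}

#' Promoter DHS fragments and their sequences
#'
#' Intersects a peak set with the strand-aware proximal promoters of the
#' annotation and extracts the overlapping fragment of each promoter
#' sequence (promoter sequences are stored as the plus-strand sequence of
#' the promoter interval). Fragments of the same promoter are unioned
#' first, so cumulative scanned length counts each base once.
#'
#' @param annotation a `gene_annotation`.
#' @param peaks peak data frame (`chrom`, `start`, `end`, `peak_id`).
#' @param promoter_seqs named sequences, one per gene id.
#' @return list with `assignment` (peak_id, gene_id pairs for every
#'   peak-promoter overlap) and `fragments` (gene_id, start, end,
#'   fragment_id, sequence).
#' @export
promoter_dhs_fragments <- function(annotation, peaks, promoter_seqs) {
  genes <- annotation$genes
  pgr <- peaks_to_granges(peaks)
  prom <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$promoter_start + 1L, genes$promoter_end))
  hits <- GenomicRanges::findOverlaps(pgr, prom)
  assignment <- data.frame(
    peak_id = peaks$peak_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  seqs <- as.character(promoter_seqs)
  frag_rows <- list()
  for (g in unique(assignment$gene_id)) {
    gi <- match(g, genes$gene_id)
    pk <- peaks[peaks$peak_id %in%
                assignment$peak_id[assignment$gene_id == g], , drop = FALSE]
    inter <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(pk$start + 1L, pk$end)),
      IRanges::IRanges(genes$promoter_start[gi] + 1L, genes$promoter_end[gi]))
    if (!length(inter)) next
    fs <- IRanges::start(inter) - 1L; fe <- IRanges::end(inter)
    local_s <- fs - genes$promoter_start[gi]
    frag_rows[[length(frag_rows) + 1L]] <- data.frame(
      gene_id = g, start = fs, end = fe,
      fragment_id = sprintf("%s_frag%d", g, seq_along(fs)),
      sequence = substring(seqs[[g]], local_s + 1L,
                           local_s + (fe - fs)),
      stringsAsFactors = FALSE)
  }
  fragments <- do.call(rbind, frag_rows) %||%
    data.frame(gene_id = character(), start = integer(), end = integer(),
               fragment_id = character(), sequence = character(),
               stringsAsFactors = FALSE)
  rownames(fragments) <- NULL
  list(assignment = assignment, fragments = fragments)
}
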