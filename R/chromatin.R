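#' Filter DHS peaks by read support and blacklisted regions
#'
#' Retains a peak iff it is covered by at least `min_reads` reads in the
#' sample AND at least `min_reads` reads in the input control, and it does
#' not overlap (by >= 1 bp) any blacklist interval. Input peaks are sorted
#' by coordinate if needed (with a message).
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based half-open)
#'   plus the two read-count columns.
#' @param min_reads minimal read count in sample and input (default 20,
#'   boundary inclusive: exactly 20 reads is kept).
#' @param blacklist optional data frame of `chrom`, `start`, `end` intervals.
#' @param sample_col,input_col names of the count columns tested.
#' @return the retained rows of `peaks`, coordinate-sorted.
#' @export
filter_dhs <- function(peaks, min_reads = 20, blacklist = NULL,
                       sample_col = "reads_sample",
                       input_col = "reads_input") {
  stopifnot(all(c("chrom", "start", "end", sample_col, input_col) %in%
                names(peaks)))
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  if (!identical(ord, seq_len(nrow(peaks)))) {
    message("filter_dhs: input peaks were unsorted; sorting by coordinate")
    peaks <- peaks[ord, , drop = FALSE]
  }
  keep <- peaks[[sample_col]] >= min_reads & peaks[[input_col]] >= min_reads
  if (!is.null(blacklist) && nrow(blacklist) > 0 && any(keep)) {
    hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks),
                                        peaks_to_granges(blacklist))
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent DHS peaks
#'
#' Collapses every chain of peaks whose successive gaps are at most
#' `max_gap` bp (boundary inclusive, transitively) into one interval
#' spanning the chain, summing the given count columns. Idempotent.
#'
#' @param peaks data frame with `chrom`, `start`, `end` and count columns.
#' @param max_gap maximal gap in bp for merging (default 100).
#' @param count_cols columns to sum across merged members (defaults to all
#'   numeric columns apart from coordinates).
#' @return merged peak data frame with a fresh `peak_id`, a `n_merged`
#'   member count, and summed count columns.
#' @export
merge_adjacent <- function(peaks, max_gap = 100, count_cols = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (is.null(count_cols)) {
    num <- vapply(peaks, is.numeric, logical(1))
    count_cols <- setdiff(names(peaks)[num], c("start", "end"))
  }
  if (!nrow(peaks)) {
    out <- peaks[, c("chrom", "start", "end", count_cols), drop = FALSE]
    out$peak_id <- character(0); out$n_merged <- integer(0)
    return(out)
  }
  gr <- peaks_to_granges(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  idx <- GenomicRanges::findOverlaps(gr, merged, maxgap = max_gap)
  member_of <- S4Vectors::subjectHits(idx)[match(seq_along(gr),
                                                S4Vectors::queryHits(idx))]
  out <- granges_to_peaks(merged)
  out$peak_id <- sprintf("merged%04d", seq_len(nrow(out)))
  out$n_merged <- as.integer(table(factor(member_of, seq_len(nrow(out)))))
  for (cc in count_cols)
    out[[cc]] <- as.vector(tapply(peaks[[cc]], factor(member_of,
                                  seq_len(nrow(out))), sum))
  out
}

#' Annotate peaks by genomic feature with fixed priority
#'
#' Assigns each peak exactly one label from promoter > 5'UTR > 3'UTR >
#' exon > intron > intergenic, where a peak gets the highest-priority
#' feature it overlaps by at least 1 bp. Promoters are the strand-aware
#' upstream windows of every transcript TSS; introns are gene bodies minus
#' exons. Peaks on chromosomes absent from the annotation are labeled
#' intergenic with a warning.
#'
#' @param peaks data frame with `chrom`, `start`, `end`.
#' @param annotation a `gene_annotation`.
#' @return character vector of labels, one per peak row.
#' @export
annotate_dhs <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  n <- nrow(peaks)
  labels <- rep("intergenic", n)
  if (!n) return(labels)
  known <- unique(annotation$genes$chrom)
  if (any(!peaks$chrom %in% known) && length(known))
    warning("peaks on chromosomes absent from annotation: labeled intergenic")
  pgr <- peaks_to_granges(peaks)

  tx <- annotation$transcripts
  prom <- data.frame(
    chrom = tx$chrom,
    start = ifelse(tx$strand == "+", tx$tss - annotation$promoter_length,
                   tx$tss + 1L),
    end = ifelse(tx$strand == "+", tx$tss,
                 tx$tss + 1L + annotation$promoter_length))
  prom$start <- pmax(prom$start, 0L)

  introns <- local({
    ex <- annotation$exons
    if (!nrow(ex)) return(ex[, c("chrom", "start", "end")])
    by_gene <- lapply(split(ex, ex$gene_id), function(d) {
      body <- IRanges::IRanges(min(d$start) + 1L, max(d$end))
      intr <- IRanges::setdiff(body, IRanges::IRanges(d$start + 1L, d$end))
      if (!length(intr)) return(NULL)
      data.frame(chrom = d$chrom[1], start = IRanges::start(intr) - 1L,
                 end = IRanges::end(intr))
    })
    do.call(rbind, Filter(Negate(is.null), by_gene)) %||%
      data.frame(chrom = character(), start = integer(), end = integer())
  })

  features <- list(promoter = prom,
                   `5'UTR` = annotation$utr5,
                   `3'UTR` = annotation$utr3,
                   exon = annotation$exons,
                   intron = introns)
  unassigned <- rep(TRUE, n)
  for (nm in names(features)) {
    f <- features[[nm]]
    if (is.null(f) || !nrow(f)) next
    # peaks on unannotated chromosomes share no seqlevels; that is the
    # already-warned intergenic case, not worth a second warning
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(pgr, peaks_to_granges(f)))
    hit_idx <- unique(S4Vectors::queryHits(hits))
    set <- hit_idx[unassigned[hit_idx]]
    labels[set] <- nm
    unassigned[set] <- FALSE
  }
  labels
}

#' Fraction of peaks in one set overlapping another
#'
#' Asymmetric benchmark: the fraction of set A peaks that overlap at least
#' one set B peak by >= 1 bp.
#'
#' @param set_a,set_b data frames with `chrom`, `start`, `end`.
#' @return numeric fraction in `[0, 1]`.
#' @export
peak_overlap_fraction <- function(set_a, set_b) {
  if (!nrow(set_a)) stop("overlap fraction undefined for an empty query set")
  if (!nrow(set_b)) return(0)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(set_a),
                                      peaks_to_granges(set_b))
  length(unique(S4Vectors::queryHits(hits))) / nrow(set_a)
}
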