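#' TSS windows per transcript
#'
#' Extends every transcript TSS by `extension` bp in both directions
#' (clipped at the chromosome bounds), the regions over which chromatin
#' openness is measured.
#'
#' @param annotation a `gene_annotation`.
#' @param extension half-window in bp (default 1000).
#' @return data frame (gene_id, transcript_id, chrom, start, end), 0-based
#'   half-open.
#' @export
tss_windows <- function(annotation, extension = 1000L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tx <- annotation$transcripts
  data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
             chrom = tx$chrom,
             start = pmax(tx$tss - extension, 0L),
             end = pmin(tx$tss + extension + 1L, annotation$chrom_length),
             stringsAsFactors = FALSE)
}

#' Reads covering each window
#'
#' Counts, for each window, the total reads of peaks overlapping it by at
#' least 1 bp (a read contributes once per window through its peak).
#'
#' @param windows data frame with `chrom`, `start`, `end`.
#' @param peaks data frame with `chrom`, `start`, `end` and a count column.
#' @param count_col name of the peak read-count column.
#' @return numeric vector of window coverages.
#' @export
count_window_reads <- function(windows, peaks, count_col) {
  out <- numeric(nrow(windows))
  if (!nrow(windows) || !nrow(peaks)) return(out)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(windows),
                                      peaks_to_granges(peaks))
  agg <- tapply(peaks[[count_col]][S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Expression-weighted TSS openness per gene
#'
#' Aggregates per-transcript TSS-window coverages into one openness value
#' per gene, weighting each transcript by its share of the gene's
#' expression in the condition under study. Fallbacks: a gene unexpressed
#' in this condition uses the other condition's weights; a gene
#' unexpressed in both uses the maximum window coverage over its
#' transcripts.
#'
#' @param annotation a `gene_annotation`.
#' @param coverage named numeric vector of window coverage per
#'   transcript_id.
#' @param expr_self named per-transcript expression in the condition being
#'   scored.
#' @param expr_other named per-transcript expression in the other
#'   condition.
#' @return data frame (gene_id, weighted_coverage, fallback) where
#'   `fallback` is `"none"`, `"other_condition"`, or `"max_coverage"`.
#' @export
tss_openness <- function(annotation, coverage, expr_self, expr_other) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tx <- annotation$transcripts
  if (!nrow(tx)) stop("annotation has no transcripts")
  missing_cov <- setdiff(tx$transcript_id, names(coverage))
  if (length(missing_cov))
    stop("coverage missing for transcripts: ",
         paste(head(missing_cov), collapse = ", "))
  rows <- lapply(split(tx$transcript_id, tx$gene_id), function(tids) {
    cov <- coverage[tids]
    e_self <- expr_self[tids]; e_other <- expr_other[tids]
    e_self[is.na(e_self)] <- 0; e_other[is.na(e_other)] <- 0
    if (sum(e_self) > 0) {
      w <- e_self / sum(e_self); fb <- "none"
    } else if (sum(e_other) > 0) {
      w <- e_other / sum(e_other); fb <- "other_condition"
    } else {
      return(data.frame(weighted_coverage = max(cov),
                        fallback = "max_coverage",
                        stringsAsFactors = FALSE))
    }
    data.frame(weighted_coverage = sum(w * cov), fallback = fb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(gene_id = names(rows), out, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[match(unique(tx$gene_id), out$gene_id), , drop = FALSE]
}

#' Classify TSSs as open or closed by the first quintile
#'
#' A gene's TSS is closed iff its weighted coverage is at or below the
#' 20th-percentile order statistic (the value at index `ceiling(0.2 n)` of
#' the sorted coverages); otherwise open. With fewer than 5 genes the
#' quintile is meaningless and every TSS is called open, with a warning.
#' Ties at the boundary are closed (inclusive rule); an all-equal input
#' therefore comes back all closed, flagged as degenerate.
#'
#' @param coverages numeric weighted TSS coverages across all genes of one
#'   cell line and condition.
#' @return character vector `"open"`/`"closed"` per gene.
#' @export
classify_tss <- function(coverages) {
  n <- length(coverages)
  if (n < 5L) {
    warning("fewer than 5 genes: quintile undefined, all TSSs called open")
    return(rep("open", n))
  }
  cut <- sort(coverages)[ceiling(0.2 * n)]
  out <- ifelse(coverages <= cut, "closed", "open")
  if (all(out == "closed"))
    warning("degenerate coverage distribution: every TSS at the boundary, ",
            "all classified closed")
  out
}
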