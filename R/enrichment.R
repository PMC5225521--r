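#' Split promoter DHSs into foreground and background sets
#'
#' The foreground is every promoter-overlapping DHS assigned to at least
#' one upregulated gene; the background is every other promoter DHS. A DHS
#' touching promoters of both an upregulated and a non-upregulated gene
#' goes to the foreground, keeping the two sets disjoint.
#'
#' @param promoter_dhs data frame with at least `peak_id` and `gene_id`
#'   (one row per peak-promoter assignment; peaks may repeat).
#' @param upregulated character vector of upregulated gene ids.
#' @return list of data frames `foreground` and `background`, each with
#'   one row per distinct peak (first assignment retained). Fails if the
#'   background is empty.
#' @export
build_background <- function(promoter_dhs, upregulated) {
  stopifnot(all(c("peak_id", "gene_id") %in% names(promoter_dhs)))
  fg_peaks <- unique(promoter_dhs$peak_id[promoter_dhs$gene_id %in%
                                          upregulated])
  is_fg <- promoter_dhs$peak_id %in% fg_peaks
  dedupe <- function(d) d[!duplicated(d$peak_id), , drop = FALSE]
  bg <- dedupe(promoter_dhs[!is_fg, , drop = FALSE])
  if (!nrow(bg))
    stop("empty background: every promoter DHS belongs to an upregulated ",
         "gene promoter")
  list(foreground = dedupe(promoter_dhs[is_fg, , drop = FALSE]),
       background = bg)
}

#' Expected binding sites from background density
#'
#' Scales the background hit count by the ratio of foreground to
#' background scanned length: `expected = background_hits /
#' background_length * foreground_length`.
#'
#' @param background_hits sites found in the background set.
#' @param background_length cumulative scanned background length in bp (> 0).
#' @param foreground_length cumulative scanned foreground length in bp.
#' @return expected site count (real).
#' @export
expected_sites <- function(background_hits, background_length,
                           foreground_length) {
  if (any(background_length <= 0)) stop("background_length must be > 0")
  background_hits / background_length * foreground_length
}

#' Enrichment ratio of observed over expected sites
#'
#' @param observed observed site count in the foreground.
#' @param expected expected site count (> 0).
#' @return ratio observed / expected.
#' @export
enrichment_ratio <- function(observed, expected) {
  if (any(expected <= 0))
    stop("ratio undefined for expected <= 0")
  observed / expected
}

#' Round half-up to a number of decimals
#'
#' Report-table rounding (2.545 -> 2.55 at two decimals), as opposed to
#' banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Background-normalized TFBS enrichment over region sets
#'
#' Scans foreground and background sequence sets with each PWM at a match
#' threshold calibrated to tail probability `p` (background base
#' frequencies estimated across all scanned sequences), then reports
#' observed, background, and expected site counts and the enrichment
#' ratio per motif.
#'
#' @param fg_seqs,bg_seqs named character vectors (or DNAStringSets) of the
#'   scanned region sequences.
#' @param pwms list of `pwm` objects (or a single one).
#' @param p match tail probability (default 0.001).
#' @param q optional background frequencies; estimated from all scanned
#'   sequences when `NULL`.
#' @return data frame (motif_id, observed_sites, background_sites,
#'   foreground_length, background_length, expected_sites, ratio); `ratio`
#'   is `NA` when no background site is found.
#' @export
tfbs_enrichment <- function(fg_seqs, bg_seqs, pwms, p = 0.001, q = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  fg_seqs <- as.character(fg_seqs); bg_seqs <- as.character(bg_seqs)
  fg_len <- sum(nchar(fg_seqs)); bg_len <- sum(nchar(bg_seqs))
  if (bg_len == 0) stop("background set is empty")
  q <- q %||% background_frequencies(c(fg_seqs, bg_seqs))
  rows <- lapply(pwms, function(pwm) {
    thr <- score_threshold(pwm, q = q, p = p)
    obs <- nrow(scan_pwm(fg_seqs, pwm, thr))
    bgh <- nrow(scan_pwm(bg_seqs, pwm, thr))
    exp_sites <- expected_sites(bgh, bg_len, fg_len)
    data.frame(motif_id = pwm$motif_id, observed_sites = obs,
               background_sites = bgh, foreground_length = fg_len,
               background_length = bg_len, expected_sites = exp_sites,
               ratio = if (exp_sites > 0) enrichment_ratio(obs, exp_sites)
                       else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select candidate regulator TFs enriched in one cell line only
#'
#' Keeps motifs whose enrichment ratio exceeds 1 in one cell line and
#' falls below 1 in the other, and whose TF is expressed (at least
#' `min_reads`) in the enriched line; ranks by the enriched-line ratio and
#' returns the top `top_k` per line.
#'
#' @param enrich_a,enrich_b enrichment tables from [tfbs_enrichment()] for
#'   the two cell lines, covering the same motifs.
#' @param tf_expression data frame (motif_id, reads_a, reads_b) of TF
#'   expression read counts per line.
#' @param min_reads expression floor in the enriched line.
#' @param top_k list length cap (default 15).
#' @return list of data frames `a` and `b` with columns motif_id, ratio,
#'   ratio_other, reads, ranked by decreasing ratio.
#' @export
select_candidates <- function(enrich_a, enrich_b, tf_expression,
                              min_reads = 1, top_k = 15) {
  stopifnot(setequal(enrich_a$motif_id, enrich_b$motif_id))
  b_ratio <- enrich_b$ratio[match(enrich_a$motif_id, enrich_b$motif_id)]
  expr <- tf_expression[match(enrich_a$motif_id, tf_expression$motif_id), ]
  pick <- function(r_self, r_other, reads) {
    ok <- !is.na(r_self) & !is.na(r_other) & r_self > 1 & r_other < 1 &
      !is.na(reads) & reads >= min_reads
    d <- data.frame(motif_id = enrich_a$motif_id[ok], ratio = r_self[ok],
                    ratio_other = r_other[ok], reads = reads[ok],
                    stringsAsFactors = FALSE)
    d <- d[order(-d$ratio), , drop = FALSE]
    rownames(d) <- NULL
    head(d, top_k)
  }
  list(a = pick(enrich_a$ratio, b_ratio, expr$reads_a),
       b = pick(b_ratio, enrich_a$ratio, expr$reads_b))
}
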