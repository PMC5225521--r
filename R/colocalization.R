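#' Co-localization of TF binding sites with consensus elements
#'
#' A TF binding site is co-localized with a consensus (SMAD-binding
#' element) occurrence when the minimal gap between the two intervals in
#' the same region is at most `window` bp (overlap counts as distance 0;
#' the boundary is inclusive, so a 201 bp gap at the default window of 200
#' is not co-localized). Enrichment is assessed with a one-sided upper
#' binomial test of the co-localized count out of all hits, against the
#' null probability that a uniformly placed match position in the scanned
#' regions would be co-localized (derived from the positional coverage of
#' the elements extended by the window on each side).
#'
#' @param tf_hits data frame (sequence_id, start, end) of TF binding
#'   sites, 0-based half-open, all of one motif width.
#' @param sbe_occurrences data frame (sequence_id, start, end) of
#'   consensus element occurrences.
#' @param region_lengths named numeric vector: length in bp of every
#'   scanned region (by sequence_id).
#' @param window co-localization distance in bp (default 200).
#' @return list with `colocalized`, `total_hits`, `null_probability`, and
#'   `p_value` (one-sided upper binomial); all-`NA` test when there are no
#'   TF hits.
#' @export
colocalization_test <- function(tf_hits, sbe_occurrences, region_lengths,
                                window = 200) {
  if (!nrow(tf_hits))
    return(list(colocalized = NA_integer_, total_hits = 0L,
                null_probability = NA_real_, p_value = NA_real_))
  w <- unique(tf_hits$end - tf_hits$start)
  if (length(w) != 1L) stop("tf_hits must come from a single motif width")
  stopifnot(all(tf_hits$sequence_id %in% names(region_lengths)),
            all(sbe_occurrences$sequence_id %in% names(region_lengths)))

  gap_le <- function(a_start, a_end, s_start, s_end)
    (s_start - a_end) <= window & (a_start - s_end) <= window
  coloc <- vapply(seq_len(nrow(tf_hits)), function(i) {
    sb <- sbe_occurrences[sbe_occurrences$sequence_id ==
                          tf_hits$sequence_id[i], , drop = FALSE]
    nrow(sb) > 0 && any(gap_le(tf_hits$start[i], tf_hits$end[i],
                               sb$start, sb$end))
  }, logical(1))

  # null: fraction of valid match offsets that would be co-localized
  total_offsets <- 0
  coloc_offsets <- 0
  for (rid in names(region_lengths)) {
    L <- region_lengths[[rid]]
    n_valid <- max(0, L - w + 1)
    if (n_valid == 0) next
    total_offsets <- total_offsets + n_valid
    sb <- sbe_occurrences[sbe_occurrences$sequence_id == rid, , drop = FALSE]
    if (!nrow(sb)) next
    lo <- pmax(sb$start - window - w, 0)
    hi <- pmin(sb$end + window, L - w)
    ok <- hi >= lo
    if (!any(ok)) next
    allowed <- IRanges::reduce(IRanges::IRanges(start = lo[ok] + 1L,
                                                end = hi[ok] + 1L))
    coloc_offsets <- coloc_offsets + sum(IRanges::width(allowed))
  }
  p0 <- if (total_offsets > 0) coloc_offsets / total_offsets else NA_real_
  k <- sum(coloc); n <- length(coloc)
  p_value <- if (is.na(p0)) NA_real_
             else pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(colocalized = as.integer(k), total_hits = as.integer(n),
       null_probability = p0, p_value = p_value)
}
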