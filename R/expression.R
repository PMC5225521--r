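#' Median-of-ratios size factors
#'
#' Computes one size factor per sample as the median, over eligible genes,
#' of the ratio between the sample's count and the gene's geometric mean
#' across samples. Genes with a zero count in any sample have geometric
#' mean zero and are excluded from the medians, as in the median-of-ratios
#' normalization popularized by DESeq.
#'
#' @param counts non-negative integer matrix, genes x samples, with unique
#'   dimnames.
#' @return object of class `size_factors`: list with `s` (named positive
#'   numeric per sample) and `excluded_genes` (ids dropped from medians).
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample colnames")
  eligible <- rowSums(counts == 0) == 0
  if (!any(eligible))
    stop("no gene with strictly positive counts in all samples; ",
         "size factors undefined")
  log_gm <- rowMeans(log(counts[eligible, , drop = FALSE]))
  s <- apply(counts[eligible, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm))
  })
  structure(list(s = s, excluded_genes = rownames(counts)[!eligible]),
            class = "size_factors")
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor, putting libraries of
#' different depth on a common scale.
#'
#' @param counts genes x samples count matrix.
#' @param factors a `size_factors` object (or named positive vector) for
#'   exactly the samples in `counts`.
#' @return numeric matrix of normalized counts, same dimnames.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as.matrix(counts)
  s <- if (inherits(factors, "size_factors")) factors$s else factors
  if (is.null(names(s)) || !setequal(names(s), colnames(counts)))
    stop("sample sets of counts and size factors differ")
  if (any(s <= 0)) stop("size factors must be positive")
  sweep(counts, 2, s[colnames(counts)], "/")
}

#' Call differentially expressed genes by dual thresholds
#'
#' A gene is differentially expressed iff both the absolute log2 ratio of
#' treated to vehicle normalized expression (with a pseudocount inside the
#' ratio only) meets `log2_min`, and the absolute difference of the
#' normalized values meets `diff_min`. No statistical test is involved;
#' this is the deterministic two-threshold rule.
#'
#' @param norm_vehicle,norm_treated named non-negative per-gene normalized
#'   expression values on the same gene set (replicate libraries should be
#'   averaged per condition first).
#' @param log2_min minimal absolute log2 ratio (default 0.75).
#' @param diff_min minimal absolute normalized-count difference (default 50).
#' @param pseudocount added to both values inside the log ratio only.
#' @return data frame (gene_id, log2_ratio, diff, direction) with one row
#'   per called gene; `direction` is `"up"` or `"down"` by the ratio sign.
#' @export
call_degs <- function(norm_vehicle, norm_treated, log2_min = 0.75,
                      diff_min = 50, pseudocount = 1) {
  if (is.null(names(norm_vehicle)) || is.null(names(norm_treated)) ||
      !identical(names(norm_vehicle), names(norm_treated)))
    stop("inputs must be named and aligned on the same gene set")
  if (any(norm_vehicle < 0) || any(norm_treated < 0))
    stop("negative normalized values rejected")
  log2_ratio <- log2((norm_treated + pseudocount) /
                     (norm_vehicle + pseudocount))
  diff <- norm_treated - norm_vehicle
  keep <- abs(log2_ratio) >= log2_min & abs(diff) >= diff_min
  out <- data.frame(gene_id = names(norm_vehicle)[keep],
                    log2_ratio = unname(log2_ratio[keep]),
                    diff = unname(diff[keep]),
                    direction = ifelse(log2_ratio[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exon-length-normalized expression density
#'
#' Divides a normalized expression value by the gene's total exon length,
#' giving reads per bp, the scale on which TSS openness is related to
#' expression.
#'
#' @param expression normalized expression value(s), >= 0.
#' @param total_exon_length exon length(s) in bp, > 0.
#' @return expression / total_exon_length.
#' @export
length_normalize <- function(expression, total_exon_length) {
  if (any(total_exon_length <= 0)) stop("total_exon_length must be > 0")
  expression / total_exon_length
}
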