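#' Simulate a unified DHS peak set with planted differential openness
#'
#' Places peaks in promoter, intronic, and intergenic compartments (the
#' default mix is intron-heavy, as typically observed for DNase
#' hypersensitive sites genome-wide), assigns each peak a base intensity,
#' and draws treated/vehicle sample reads and input-control reads from
#' Poisson models. A chosen subset of peaks has its treated-condition
#' intensity multiplied by `openness_fold`, emulating condition-specific
#' chromatin opening.
#'
#' @param annotation a `gene_annotation` used for compartment placement.
#' @param n_peaks total number of peaks.
#' @param n_diff number of peaks with planted differential openness.
#' @param openness_fold multiplicative treated-intensity fold (> 0).
#' @param seed integer seed (substream-expanded).
#' @param proportions named numeric proportions for compartments
#'   `promoter`, `intron`, `intergenic` (normalized internally).
#' @param base_intensity mean Poisson intensity of sample reads per peak.
#' @param input_intensity mean Poisson intensity of input-control reads.
#' @param width_range min/max peak width in bp.
#' @param promoter_intensity optional named vector (by gene_id); when given,
#'   promoter-compartment peak intensities are scaled proportionally to it
#'   so TSS openness tracks expression.
#' @return list with `peaks` — data frame (peak_id, chrom, start, end,
#'   compartment, gene_id, reads_treated, reads_vehicle,
#'   input_treated, input_vehicle) in 0-based half-open coordinates — and
#'   `truth` with `diff_dhs` (peak_id, openness_fold).
#' @export
generate_dhs <- function(annotation, n_peaks, n_diff = 0L,
                         openness_fold = 4, seed = 1L,
                         proportions = c(promoter = 0.15, intron = 0.55,
                                         intergenic = 0.30),
                         base_intensity = 80, input_intensity = 60,
                         width_range = c(150L, 400L),
                         promoter_intensity = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  assert_scalar_number(n_peaks, "n_peaks", min = 0)
  assert_scalar_number(n_diff, "n_diff", min = 0, max = n_peaks)
  if (!is.finite(openness_fold) || openness_fold <= 0)
    stop("openness_fold must be > 0")
  set.seed(substream_seed(seed, "dhs"))

  genes <- annotation$genes
  props <- proportions / sum(proportions)
  compartments <- sample(names(props), n_peaks, replace = TRUE, prob = props)

  # intergenic space = chromosome minus gene footprints (promoter + body)
  foot <- IRanges::reduce(IRanges::IRanges(
    start = pmin(genes$promoter_start, genes$start) + 1L,
    end = pmax(genes$promoter_end, genes$end)))
  gaps <- IRanges::gaps(foot, start = 1L, end = annotation$chrom_length)

  introns_by_gene <- lapply(split(annotation$exons, annotation$exons$gene_id),
    function(d) {
      body <- IRanges::IRanges(min(d$start) + 1L, max(d$end))
      IRanges::setdiff(body, IRanges::IRanges(d$start + 1L, d$end))
    })

  place_in <- function(ir, width) {
    ok <- IRanges::width(ir) >= width
    if (!any(ok)) return(NA_integer_)
    pick <- which(ok)[sample.int(sum(ok), 1L)]
    lo <- IRanges::start(ir)[pick] - 1L
    hi <- IRanges::end(ir)[pick] - width
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }

  n <- n_peaks
  width <- if (n) sample(width_range[1]:width_range[2], n, replace = TRUE) else integer(0)
  start <- integer(n); gene_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    comp <- compartments[i]
    if (comp == "promoter" && nrow(genes)) {
      g <- sample.int(nrow(genes), 1L)
      w <- min(width[i], annotation$promoter_length)
      width[i] <- w
      start[i] <- genes$promoter_start[g] +
        sample.int(annotation$promoter_length - w + 1L, 1L) - 1L
      gene_id[i] <- genes$gene_id[g]
    } else if (comp == "intron" && length(introns_by_gene)) {
      g <- sample(names(introns_by_gene), 1L)
      s <- place_in(introns_by_gene[[g]], width[i])
      if (is.na(s)) { compartments[i] <- "intergenic"
                      s <- place_in(gaps, width[i]) }
      else gene_id[i] <- g
      start[i] <- s
    } else {
      compartments[i] <- "intergenic"
      start[i] <- place_in(gaps, width[i])
    }
    if (is.na(start[i])) stop("no room to place peak; enlarge chromosome")
  }

  intensity <- base_intensity * stats::rlnorm(n, 0, 0.4)
  if (!is.null(promoter_intensity)) {
    hit <- compartments == "promoter" & gene_id %in% names(promoter_intensity)
    scale <- promoter_intensity / mean(promoter_intensity)
    intensity[hit] <- base_intensity * scale[gene_id[hit]]
  }
  diff_idx <- if (n_diff > 0) sort(sample.int(n, n_diff)) else integer(0)
  fold <- rep(1, n); fold[diff_idx] <- openness_fold

  peaks <- data.frame(
    peak_id = sprintf("dhs%04d", seq_len(n)),
    chrom = if (nrow(genes)) genes$chrom[1] else "chr1",
    start = start, end = start + width,
    compartment = compartments, gene_id = gene_id,
    reads_treated = rpois(n, intensity * fold),
    reads_vehicle = rpois(n, intensity),
    input_treated = rpois(n, input_intensity),
    input_vehicle = rpois(n, input_intensity),
    stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL

  list(peaks = peaks,
       truth = list(diff_dhs = data.frame(
         peak_id = sprintf("dhs%04d", diff_idx),
         openness_fold = rep(openness_fold, length(diff_idx)),
         stringsAsFactors = FALSE)))
}
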