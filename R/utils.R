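#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-generator substream seed from one global seed
#'
#' Each synthetic-data generator consumes its own substream so that adding or
#' reordering generators never perturbs the draws of the others. The mapping
#' is a fixed affine hash of the global seed and a registered stream name,
#' reduced modulo 2^31 - 1 so the result is always a valid integer seed.
#'
#' @param seed integer global seed.
#' @param stream character, one of the registered generator stream names.
#' @return integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stream = c("annotation", "counts", "dhs",
                                            "promoters", "survival",
                                            "pipeline")) {
  stream <- match.arg(stream)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offset <- c(annotation = 1L, counts = 2L, dhs = 3L, promoters = 4L,
              survival = 5L, pipeline = 6L)[[stream]]
  # doubles are exact well beyond this product; keep below 2^31 - 1
  as.integer((abs(seed) * 48271 + offset * 16807) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  if (x > max)
    stop(sprintf("`%s` must be <= %g", name, max), call. = FALSE)
  invisible(x)
}

#' @keywords internal
#' @noRd
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

#' @keywords internal
#' @noRd
granges_to_peaks <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
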