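# Hand-built annotation objects with exact coordinates, for tests that need
# full control over gene/transcript/exon placement (0-based half-open).

manual_annotation <- function(genes, transcripts, exons,
                              utr5 = empty_feat(), utr3 = empty_feat(),
                              chrom_length = 100000L,
                              promoter_length = 2000L) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 utr5 = utr5, utr3 = utr3,
                 chrom_length = as.integer(chrom_length),
                 promoter_length = as.integer(promoter_length)),
            class = "gene_annotation")
}

empty_feat <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

# one plus-strand gene at [10000, 16000) with two transcripts
two_tx_annotation <- function() {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+",
                      start = 10000L, end = 16000L, tss = 10000L,
                      promoter_start = 8000L, promoter_end = 10000L,
                      stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = "gA", transcript_id = c("gA.t1", "gA.t2"),
                   chrom = "chr1", strand = "+",
                   start = c(10000L, 10400L), end = 16000L,
                   tss = c(10000L, 10400L), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "gA",
                      transcript_id = c("gA.t1", "gA.t1", "gA.t2", "gA.t2"),
                      chrom = "chr1", strand = "+",
                      start = c(10000L, 12000L, 10400L, 12000L),
                      end = c(11000L, 16000L, 11000L, 16000L),
                      stringsAsFactors = FALSE)
  manual_annotation(genes, tx, exons)
}

motif_file <- function(name) {
  system.file("extdata", "motifs", name, package = "dhsreg")
}

uniform_q <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

peak_df <- function(start, end, chrom = "chr1", ...) {
  data.frame(chrom = chrom, start = start, end = end,
             peak_id = sprintf("p%03d", seq_along(start)), ...,
             stringsAsFactors = FALSE)
}
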