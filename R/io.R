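#' Write / read a count matrix as TSV
#'
#' Plain TSV with a `gene_id` first column and one column per sample.
#'
#' @param counts genes x samples matrix.
#' @param path file path.
#' @return `read_counts_tsv` returns an integer matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a peak table as BED with extra count columns
#'
#' BED6 layout (chrom, start, end, name, score = 0, strand = `.`) followed
#' by the requested count columns. Coordinates are written natively
#' (0-based half-open, as BED).
#'
#' @param peaks peak data frame with `chrom`, `start`, `end`, `peak_id`.
#' @param path file path.
#' @param count_cols extra numeric columns to append.
#' @return `read_peaks_bed` returns the peak data frame.
#' @export
write_peaks_bed <- function(peaks, path,
                            count_cols = intersect(
                              c("reads_treated", "reads_vehicle",
                                "input_treated", "input_vehicle"),
                              names(peaks))) {
  df <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   name = peaks$peak_id, score = 0L, strand = ".",
                   stringsAsFactors = FALSE)
  for (cc in count_cols) df[[cc]] <- peaks[[cc]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @param col_names names of the extra columns, in file order.
#' @export
read_peaks_bed <- function(path, col_names = c("reads_treated",
                                               "reads_vehicle",
                                               "input_treated",
                                               "input_vehicle")) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  n_extra <- ncol(df) - 6L
  names(df) <- c("chrom", "start", "end", "peak_id", "score", "strand",
                 col_names[seq_len(n_extra)])
  df$score <- NULL; df$strand <- NULL
  df
}

#' Write / read a gene annotation as GTF
#'
#' Exports gene, transcript, and exon features (1-based inclusive, as GTF)
#' through rtracklayer; internal 0-based half-open coordinates are
#' converted on the way. Reading reconstructs a `gene_annotation`;
#' promoter windows, UTRs, and the chromosome length are rebuilt from the
#' read features and the supplied parameters.
#'
#' @param annotation a `gene_annotation`.
#' @param path GTF file path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  mk <- function(df, type) {
    if (!nrow(df)) return(NULL)
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(df$start + 1L, df$end),
      strand = df$strand,
      type = type, gene_id = df$gene_id,
      transcript_id = if ("transcript_id" %in% names(df)) df$transcript_id
                      else df$gene_id)
  }
  gr <- c(mk(annotation$genes, "gene"),
          mk(annotation$transcripts, "transcript"),
          mk(annotation$exons, "exon"),
          mk(annotation$utr5, "five_prime_utr"),
          mk(annotation$utr3, "three_prime_utr"))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @param chrom_length chromosome length to record (default: max feature
#'   end plus the promoter length).
#' @param promoter_length promoter window length in bp.
#' @export
read_annotation_gtf <- function(path, chrom_length = NULL,
                                promoter_length = 2000L) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = gr$type, gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  pick <- function(type, keep_tx = TRUE) {
    d <- df[df$type == type,
            c("gene_id", "transcript_id", "chrom", "strand", "start", "end")]
    if (!keep_tx) d$transcript_id <- NULL
    rownames(d) <- NULL
    d
  }
  genes <- pick("gene", keep_tx = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$promoter_start <- ifelse(genes$strand == "+",
                                 genes$start - promoter_length, genes$end)
  genes$promoter_end <- genes$promoter_start + promoter_length
  tx <- pick("transcript")
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  ann <- list(genes = genes, transcripts = tx, exons = pick("exon"),
              utr5 = pick("five_prime_utr"), utr3 = pick("three_prime_utr"),
              chrom_length = as.integer(chrom_length %||%
                (max(df$end) + promoter_length)),
              promoter_length = as.integer(promoter_length))
  class(ann) <- "gene_annotation"
  ann
}

#' Write promoter sequences as FASTA
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param path FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Write synthetic ground truth as JSON
#'
#' @param truth list of truth records from the generators.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a stage output TSV with a self-describing header
#'
#' Prepends a comment line carrying the stage name and the configuration
#' hash so every output is traceable to the run that produced it, then the
#' column header and rows.
#'
#' @param df data frame to write.
#' @param path file path.
#' @param stage stage name recorded in the header.
#' @param config_hash hash string from [config_hash()].
#' @export
write_stage_tsv <- function(df, path, stage, config_hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dhsreg stage=%s config_hash=%s rows=%d",
                     stage, config_hash, nrow(df)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
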