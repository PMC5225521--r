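#' Generate a synthetic gene annotation with known structure
#'
#' Places non-overlapping gene models on a single synthetic chromosome. Each
#' gene carries one or more transcripts with alternative transcription start
#' sites (TSSs), exon/intron structure, and terminal UTR segments, plus a
#' strand-aware proximal promoter (by default the 2000 bp immediately
#' upstream of the gene's 5'-most TSS). Coordinates are 0-based, half-open.
#' The full gene footprint (promoter plus gene body) is kept pairwise
#' disjoint and inside the chromosome, so every promoter is well defined.
#'
#' @param n_genes number of genes to place (0 gives an empty annotation).
#' @param transcripts_per_gene transcripts per gene; alternative TSSs are
#'   offset downstream of the gene TSS by at most `tss_spread` bp.
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed; a substream is derived via [substream_seed()].
#' @param chrom chromosome name.
#' @param promoter_length promoter length in bp upstream of the TSS.
#' @param gene_length_range min/max gene body length in bp.
#' @param exons_per_transcript target exon count per transcript (reduced for
#'   short transcripts).
#' @param tss_spread maximal downstream offset of alternative TSSs in bp.
#' @param utr_length terminal UTR length in bp (capped at half the terminal
#'   exon).
#' @return an object of class `gene_annotation`: a list with data frames
#'   `genes` (gene_id, chrom, strand, start, end, tss, promoter_start,
#'   promoter_end), `transcripts`, `exons`, `utr5`, `utr3`, and scalars
#'   `chrom_length`, `promoter_length`.
#' @export
generate_annotation <- function(n_genes, transcripts_per_gene = 1L,
                                chrom_length = 1e6, seed = 1L,
                                chrom = "chr1", promoter_length = 2000L,
                                gene_length_range = c(2000L, 8000L),
                                exons_per_transcript = 3L,
                                tss_spread = 500L, utr_length = 100L) {
  assert_scalar_number(n_genes, "n_genes", min = 0)
  assert_scalar_number(chrom_length, "chrom_length", min = 1)
  assert_scalar_number(transcripts_per_gene, "transcripts_per_gene", min = 1)
  set.seed(substream_seed(seed, "annotation"))

  genes <- transcripts <- exons <- utr5 <- utr3 <- list()
  placed <- IRanges::IRanges()
  max_tries <- 200L * max(1L, n_genes)
  tries <- 0L

  i <- 1L
  while (i <= n_genes) {
    len <- sample(gene_length_range[1]:gene_length_range[2], 1L)
    strand <- sample(c("+", "-"), 1L)
    footprint <- len + promoter_length
    if (footprint >= chrom_length)
      stop("chrom_length too small to place genes without overlap")
    fp_start <- sample.int(chrom_length - footprint, 1L) - 1L
    g_start <- if (strand == "+") fp_start + promoter_length else fp_start
    g_end <- g_start + len
    cand <- IRanges::IRanges(fp_start + 1L, fp_start + footprint)
    tries <- tries + 1L
    if (length(placed) && length(IRanges::findOverlaps(cand, placed)) > 0) {
      if (tries > max_tries)
        stop("chrom_length too small to place genes without overlap")
      next
    }
    placed <- c(placed, cand)
    gid <- sprintf("gene%03d", i)
    tss <- if (strand == "+") g_start else g_end - 1L
    prom <- if (strand == "+") c(g_start - promoter_length, g_start)
            else c(g_end, g_end + promoter_length)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = g_start, end = g_end, tss = tss,
                             promoter_start = prom[1], promoter_end = prom[2],
                             stringsAsFactors = FALSE)
    tx <- make_transcripts(gid, chrom, strand, g_start, g_end,
                           transcripts_per_gene, exons_per_transcript,
                           tss_spread, utr_length)
    transcripts[[i]] <- tx$transcripts
    exons[[i]] <- tx$exons
    utr5[[i]] <- tx$utr5
    utr3[[i]] <- tx$utr3
    i <- i + 1L
  }

  bind <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lst)
  }
  empty_genes <- data.frame(gene_id = character(), chrom = character(),
                            strand = character(), start = integer(),
                            end = integer(), tss = integer(),
                            promoter_start = integer(),
                            promoter_end = integer(), stringsAsFactors = FALSE)
  ann <- list(
    genes = bind(genes) %||% empty_genes,
    transcripts = bind(transcripts) %||% data.frame(),
    exons = bind(exons) %||% data.frame(),
    utr5 = bind(utr5) %||% data.frame(),
    utr3 = bind(utr3) %||% data.frame(),
    chrom_length = as.integer(chrom_length),
    promoter_length = as.integer(promoter_length)
  )
  rownames(ann$genes) <- NULL
  class(ann) <- "gene_annotation"
  ann
}

# Exon/intron structure for one gene: alternating segments of at least
# `min_seg` bp partition each transcript span; transcript 1 starts at the
# gene's 5' end so the gene TSS is the 5'-most transcript coordinate.
make_transcripts <- function(gid, chrom, strand, g_start, g_end,
                             n_tx, n_exons, tss_spread, utr_length,
                             min_seg = 30L) {
  tx_list <- ex_list <- u5_list <- u3_list <- list()
  len <- g_end - g_start
  for (t in seq_len(n_tx)) {
    off <- if (t == 1L) 0L else sample.int(min(tss_spread, len %/% 2L), 1L)
    if (strand == "+") { t_start <- g_start + off; t_end <- g_end }
    else { t_start <- g_start; t_end <- g_end - off }
    span <- t_end - t_start
    k <- max(1L, min(n_exons, span %/% (2L * min_seg)))
    nseg <- 2L * k - 1L
    extra <- stats::rmultinom(1L, span - nseg * min_seg, rep(1, nseg))[, 1]
    seg <- min_seg + extra
    bounds <- t_start + cumsum(c(0L, seg))
    ex_idx <- seq(1L, nseg, by = 2L)
    ex <- data.frame(gene_id = gid,
                     transcript_id = sprintf("%s.t%d", gid, t),
                     chrom = chrom, strand = strand,
                     start = bounds[ex_idx], end = bounds[ex_idx + 1L],
                     stringsAsFactors = FALSE)
    tss <- if (strand == "+") t_start else t_end - 1L
    tx_list[[t]] <- data.frame(gene_id = gid,
                               transcript_id = sprintf("%s.t%d", gid, t),
                               chrom = chrom, strand = strand,
                               start = t_start, end = t_end, tss = tss,
                               stringsAsFactors = FALSE)
    ex_list[[t]] <- ex
    first_ex <- ex[1, ]; last_ex <- ex[nrow(ex), ]
    if (strand == "+") {
      u5len <- min(utr_length, (first_ex$end - first_ex$start) %/% 2L)
      u3len <- min(utr_length, (last_ex$end - last_ex$start) %/% 2L)
      u5 <- c(first_ex$start, first_ex$start + u5len)
      u3 <- c(last_ex$end - u3len, last_ex$end)
    } else {
      u5len <- min(utr_length, (last_ex$end - last_ex$start) %/% 2L)
      u3len <- min(utr_length, (first_ex$end - first_ex$start) %/% 2L)
      u5 <- c(last_ex$end - u5len, last_ex$end)
      u3 <- c(first_ex$start, first_ex$start + u3len)
    }
    u5_list[[t]] <- data.frame(gene_id = gid,
                               transcript_id = sprintf("%s.t%d", gid, t),
                               chrom = chrom, strand = strand,
                               start = u5[1], end = u5[2],
                               stringsAsFactors = FALSE)
    u3_list[[t]] <- data.frame(gene_id = gid,
                               transcript_id = sprintf("%s.t%d", gid, t),
                               chrom = chrom, strand = strand,
                               start = u3[1], end = u3[2],
                               stringsAsFactors = FALSE)
  }
  list(transcripts = do.call(rbind, tx_list),
       exons = do.call(rbind, ex_list),
       utr5 = do.call(rbind, u5_list),
       utr3 = do.call(rbind, u3_list))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d transcripts, %d exons on %s (%d bp)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              if (nrow(x$genes)) x$genes$chrom[1] else "<empty>",
              x$chrom_length))
  invisible(x)
}

#' Total exon length per gene
#'
#' Sums the widths of the union of a gene's exons over all its transcripts,
#' the denominator used when converting normalized expression to an
#' exon-length-normalized density.
#'
#' @param annotation a `gene_annotation`.
#' @return named numeric vector of total exon length (bp) per gene.
#' @export
total_exon_length <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  if (!nrow(ex)) return(setNames(numeric(0), character(0)))
  out <- vapply(split(ex, ex$gene_id), function(d) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(d$start + 1L, d$end))))
  }, numeric(1))
  out[unique(annotation$genes$gene_id)]
}
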