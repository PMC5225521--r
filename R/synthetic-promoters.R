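#' Simulate promoter sequences with planted motif occurrences
#'
#' Emits one promoter sequence per gene: i.i.d. background bases at a stated
#' GC content, with consensus motif strings inserted at recorded offsets.
#' Promoters of a designated foreground gene set receive insertions at rate
#' `planted_rate_fg`, all others at `planted_rate_bg` (expected insertions
#' per promoter, Poisson). Insertions never overlap each other; IUPAC `n`
#' positions in the consensus are resolved to random concrete bases.
#'
#' @param annotation a `gene_annotation` (promoter length is taken from it).
#' @param motif consensus string to insert (A/C/G/T plus `n`).
#' @param planted_rate_fg expected insertions per foreground promoter.
#' @param planted_rate_bg expected insertions per background promoter.
#' @param gc background GC fraction, strictly between 0 and 1.
#' @param seed integer seed (substream-expanded).
#' @param fg_genes character vector of foreground gene ids.
#' @param motif_id label recorded for planted occurrences.
#' @return list with `sequences` (a named [Biostrings::DNAStringSet], one
#'   promoter per gene), and `truth` with `motif_positions` (sequence_id,
#'   offset 0-based, motif_id) and `fg_genes`.
#' @export
generate_promoters <- function(annotation, motif, planted_rate_fg = 0,
                               planted_rate_bg = 0, gc = 0.41, seed = 1L,
                               fg_genes = character(0),
                               motif_id = "planted") {
  stopifnot(inherits(annotation, "gene_annotation"))
  assert_scalar_number(planted_rate_fg, "planted_rate_fg", min = 0)
  assert_scalar_number(planted_rate_bg, "planted_rate_bg", min = 0)
  assert_scalar_number(gc, "gc", min = 0, max = 1)
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  motif <- toupper(motif)
  if (!grepl("^[ACGTN]+$", motif)) stop("motif must be over A/C/G/T/n")
  L <- annotation$promoter_length
  w <- nchar(motif)
  if (w > L) stop("motif longer than promoter rejected")
  set.seed(substream_seed(seed, "promoters"))

  gids <- annotation$genes$gene_id
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- character(length(gids))
  pos_list <- list()
  for (i in seq_along(gids)) {
    s <- sample(names(probs), L, replace = TRUE, prob = probs)
    rate <- if (gids[i] %in% fg_genes) planted_rate_fg else planted_rate_bg
    k <- if (rate > 0) rpois(1L, rate) else 0L
    used <- IRanges::IRanges()
    placed <- integer(0)
    tries <- 0L
    while (length(placed) < k && tries < 50L * max(1L, k)) {
      tries <- tries + 1L
      off <- sample.int(L - w + 1L, 1L) - 1L
      cand <- IRanges::IRanges(off + 1L, off + w)
      if (length(used) && length(IRanges::findOverlaps(cand, used)) > 0) next
      used <- c(used, cand)
      placed <- c(placed, off)
      ins <- strsplit(motif, "")[[1]]
      ins[ins == "N"] <- sample(c("A", "C", "G", "T"), sum(ins == "N"),
                                replace = TRUE)
      s[(off + 1L):(off + w)] <- ins
    }
    if (length(placed))
      pos_list[[length(pos_list) + 1L]] <- data.frame(
        sequence_id = gids[i], offset = sort(placed), motif_id = motif_id,
        stringsAsFactors = FALSE)
    seqs[i] <- paste(s, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(setNames(seqs, gids))
  motif_positions <- if (length(pos_list)) do.call(rbind, pos_list)
    else data.frame(sequence_id = character(), offset = integer(),
                    motif_id = character(), stringsAsFactors = FALSE)
  rownames(motif_positions) <- NULL
  list(sequences = sequences,
       truth = list(motif_positions = motif_positions, fg_genes = fg_genes))
}
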