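#' Scan sequences for PWM matches on both strands
#'
#' Slides the PWM over every valid offset of each sequence and reports
#' positions whose match score reaches the calibrated threshold. The
#' reverse strand is scanned with the reverse-complemented matrix, so
#' reverse hits are reported in forward coordinates. Windows containing an
#' ambiguous base yield no hit; sequences shorter than the motif yield
#' zero hits without error.
#'
#' @param sequences a [Biostrings::DNAStringSet] or named character vector.
#' @param pwm a `pwm`.
#' @param threshold score threshold (from [score_threshold()]).
#' @param strands `"both"` (default), `"+"`, or `"-"`.
#' @return data frame (sequence_id, start, end, strand, score, motif_id)
#'   with 0-based half-open forward coordinates.
#' @export
scan_pwm <- function(sequences, pwm, threshold,
                     strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"))
  empty_hits <- data.frame(sequence_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           score = numeric(), motif_id = character(),
                           stringsAsFactors = FALSE)
  if (!length(sequences)) return(empty_hits)
  nms <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- nms %||% paste0("seq", seq_along(seqs))
  w <- pwm$w
  S_fwd <- pwm$S
  # reverse strand: complement the rows and reverse the columns
  S_rev <- S_fwd[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(S_rev) <- c("A", "C", "G", "T")

  one_strand <- function(codes, S) {
    L <- length(codes)
    if (L < w) return(data.frame(start = integer(), score = numeric()))
    M <- numeric(L - w + 1L)
    for (i in seq_len(w))
      M <- M + S[cbind(codes[i:(L - w + i)], i)]
    hit <- !is.na(M) & M >= threshold
    data.frame(start = which(hit) - 1L, score = M[hit])
  }

  out <- lapply(names(seqs), function(id) {
    codes <- match(strsplit(toupper(seqs[[id]]), "")[[1]],
                   c("A", "C", "G", "T"))
    res <- list()
    if (strands %in% c("both", "+")) {
      h <- one_strand(codes, S_fwd)
      if (nrow(h)) res[["+"]] <- data.frame(h, strand = "+")
    }
    if (strands %in% c("both", "-")) {
      h <- one_strand(codes, S_rev)
      if (nrow(h)) res[["-"]] <- data.frame(h, strand = "-")
    }
    if (!length(res)) return(NULL)
    h <- do.call(rbind, res)
    data.frame(sequence_id = id, start = h$start, end = h$start + w,
               strand = h$strand, score = h$score, motif_id = pwm$motif_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out)) %||% empty_hits
  rownames(out) <- NULL
  out[order(out$sequence_id, out$start, out$strand), , drop = FALSE]
}

#' Find exact IUPAC consensus occurrences on both strands
#'
#' Locates every exact occurrence of each consensus pattern (IUPAC codes,
#' `n` = any base) on the forward and reverse strands, reporting forward
#' coordinates. Palindromic matches found on both strands are reported
#' once, on the forward strand.
#'
#' @param sequences a [Biostrings::DNAStringSet] or named character vector.
#' @param patterns character vector of IUPAC consensus strings.
#' @return data frame (sequence_id, start, end, strand, pattern), 0-based
#'   half-open.
#' @export
find_consensus <- function(sequences, patterns) {
  empty_occ <- data.frame(sequence_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          pattern = character(), stringsAsFactors = FALSE)
  if (!length(sequences)) return(empty_occ)
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  res <- list()
  for (pat in patterns) {
    p <- Biostrings::DNAString(toupper(pat))
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") p else Biostrings::reverseComplement(p)
      m <- Biostrings::vmatchPattern(probe, sequences, fixed = FALSE)
      for (i in seq_along(m)) {
        ir <- m[[i]]
        if (!length(ir)) next
        res[[length(res) + 1L]] <- data.frame(
          sequence_id = names(sequences)[i],
          start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
          strand = strand, pattern = pat, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res) %||% empty_occ
  # palindromes match identically on both strands: keep the forward report
  out <- out[!duplicated(out[, c("sequence_id", "start", "end", "pattern")]), ]
  rownames(out) <- NULL
  out[order(out$pattern, out$sequence_id, out$start), , drop = FALSE]
}

#' The six SMAD-binding-element consensus sequences
#'
#' Short consensus elements recognized by SMAD transcription factors, used
#' for co-localization testing: CAGACA, GTCT, CAGC, CGCC, GGCGCC, and
#' GCCGnCGC.
#'
#' @return character vector of IUPAC patterns.
#' @export
sbe_patterns <- function() {
  c("CAGACA", "GTCT", "CAGC", "CGCC", "GGCGCC", "GCCGNCGC")
}
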