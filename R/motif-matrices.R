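#' Read a weighted positional count matrix (WPCM)
#'
#' Parses a plain-text matrix in the HOCOMOCO style: a header line
#' `>MOTIF_ID [width]`, followed by one row per motif position holding four
#' whitespace-separated non-negative numbers in A C G T order. The total
#' weight W is the sum of the first position's counts; every position must
#' sum to W within a relative tolerance of 1e-6 (WPCMs carry fractional,
#' weighted counts, hence the numeric tolerance).
#'
#' @param path file with exactly one matrix.
#' @return object of class `wpcm`: list with `motif_id`, `counts` (4 x w
#'   matrix, rows A,C,G,T), and `W`.
#' @export
read_wpcm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("expected a '>MOTIF_ID' header line")
  header <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
  motif_id <- header[1]
  declared_w <- if (length(header) > 1) as.integer(header[2]) else NA_integer_
  rows <- lapply(lines[-1], function(l) {
    vals <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (length(vals) != 4L || anyNA(vals))
      stop("malformed matrix row: ", l)
    vals
  })
  if (!length(rows)) stop("matrix has no positions")
  if (!is.na(declared_w) && declared_w != length(rows))
    stop(sprintf("header declares %d positions but %d rows found",
                 declared_w, length(rows)))
  counts <- t(do.call(rbind, rows))
  rownames(counts) <- c("A", "C", "G", "T")
  colnames(counts) <- NULL
  if (any(counts < 0)) stop("negative counts rejected")
  W <- sum(counts[, 1])
  csum <- colSums(counts)
  if (any(abs(csum - W) > 1e-6 * max(W, 1)))
    stop("inconsistent column sums: total weight must be constant")
  new_wpcm(motif_id, counts, W)
}

new_wpcm <- function(motif_id, counts, W = sum(counts[, 1])) {
  structure(list(motif_id = motif_id, counts = counts, W = W,
                 w = ncol(counts)), class = "wpcm")
}

#' Write a WPCM to a plain-text file
#'
#' Inverse of [read_wpcm()]; round-trips exactly at 10 significant digits.
#'
#' @param wpcm a `wpcm` object.
#' @param path output file.
#' @export
write_wpcm <- function(wpcm, path) {
  stopifnot(inherits(wpcm, "wpcm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(">%s %d", wpcm$motif_id, wpcm$w), con)
  apply(wpcm$counts, 2, function(col)
    writeLines(paste(format(col, digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = "\t"), con))
  invisible(path)
}

#' @export
print.wpcm <- function(x, ...) {
  cat(sprintf("wpcm %s: width %d, total weight %.4g\n", x$motif_id, x$w, x$W))
  invisible(x)
}

#' Build a position weight matrix from a WPCM
#'
#' Converts weighted positional counts into natural-log odds scores
#' \deqn{S_{b,i} = \ln\frac{x_{b,i} + a q_b}{(W + a) q_b}}
#' with pseudocount `a = ln(W)` and background base frequencies `q`. W must
#' exceed 1 so the pseudocount is positive.
#'
#' @param wpcm a `wpcm`.
#' @param q named background frequencies for A, C, G, T; strictly positive,
#'   summing to 1.
#' @return object of class `pwm`: list with `motif_id`, `S` (4 x w log-odds
#'   matrix), `a`, `q`, `w`.
#' @export
build_pwm <- function(wpcm, q = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(wpcm, "wpcm"))
  q <- q[c("A", "C", "G", "T")]
  if (anyNA(q) || any(q <= 0) || abs(sum(q) - 1) > 1e-8)
    stop("q must be strictly positive frequencies for A,C,G,T summing to 1")
  if (wpcm$W <= 1) stop("total weight W must exceed 1 (pseudocount ln(W) > 0)")
  a <- log(wpcm$W)
  S <- log((wpcm$counts + a * q) / ((wpcm$W + a) * q))
  structure(list(motif_id = wpcm$motif_id, S = S, a = a, q = q,
                 w = wpcm$w), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, pseudocount %.4f\n", x$motif_id, x$w, x$a))
  invisible(x)
}

#' Background base frequencies of a sequence set
#'
#' Counts A/C/G/T on the forward strands of the given sequences, excluding
#' ambiguous bases; falls back to the uniform distribution when no
#' unambiguous base is present.
#'
#' @param sequences a [Biostrings::DNAStringSet] or named character vector.
#' @return named frequency vector over A, C, G, T.
#' @export
background_frequencies <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!length(sequences))
    return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  freq <- colSums(Biostrings::alphabetFrequency(sequences))[c("A", "C", "G", "T")]
  if (sum(freq) == 0) return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  freq / sum(freq)
}
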