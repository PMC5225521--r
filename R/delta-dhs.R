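#' Differential hypersensitivity change score (deltaDHS)
#'
#' For a unified set of m DHSs with read counts in a treated and a vehicle
#' condition, the change score of site i is
#' \deqn{\Delta_i = \sqrt{n_i^{treated} / (\Sigma^{treated}/m)} -
#'       \sqrt{n_i^{vehicle} / (\Sigma^{vehicle}/m)}}
#' i.e. each count is scaled by the mean reads-per-DHS of its condition
#' before the square-root transform. This symmetric form is antisymmetric
#' under swapping the condition labels. A condition with zero total reads
#' contributes 0 to every score, with a warning.
#'
#' @param reads_treated,reads_vehicle non-negative counts over the same
#'   unified peak set (m >= 1).
#' @return numeric vector of deltaDHS scores, one per peak.
#' @export
delta_dhs <- function(reads_treated, reads_vehicle) {
  m <- length(reads_treated)
  if (m < 1L || length(reads_vehicle) != m)
    stop("need matched counts over a unified peak set of size >= 1")
  if (any(reads_treated < 0) || any(reads_vehicle < 0))
    stop("counts must be non-negative")
  term <- function(n) {
    tot <- sum(n)
    if (tot == 0) {
      warning("zero total reads in one condition: its term is 0")
      return(rep(0, m))
    }
    sqrt(n / (tot / m))
  }
  term(reads_treated) - term(reads_vehicle)
}

#' Select differential DHSs by score threshold
#'
#' Keeps sites with deltaDHS at or above the threshold (opening sites), or
#' at or below its negative when the closing direction is requested. The
#' boundary is inclusive.
#'
#' @param scores deltaDHS scores.
#' @param threshold selection threshold (default 0.20).
#' @param direction `"opening"` (default), `"closing"`, or `"both"` for
#'   absolute-value selection.
#' @return logical vector marking selected sites.
#' @export
select_differential <- function(scores, threshold = 0.20,
                                direction = c("opening", "closing", "both")) {
  direction <- match.arg(direction)
  switch(direction,
         opening = scores >= threshold,
         closing = scores <= -threshold,
         both = abs(scores) >= threshold)
}
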