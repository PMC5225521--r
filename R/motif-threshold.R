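#' Exact PWM score distribution under an i.i.d. background
#'
#' Computes the exact distribution of the match score of a random w-mer
#' drawn i.i.d. from the background `q`, by dynamic programming over
#' scores discretized to a grid of `eps` log-units: column scores are
#' rounded to integer multiples of `eps` and the distribution of their sum
#' is built by successive convolution. The discretization error of any
#' single word score is at most `w * eps / 2`.
#'
#' @param pwm a `pwm`.
#' @param q background frequencies (defaults to the PWM's own `q`).
#' @param eps score discretization step in log-units.
#' @return data frame (`score`, `prob`) over achievable discretized
#'   scores, ascending; probabilities sum to 1.
#' @export
pwm_score_distribution <- function(pwm, q = NULL, eps = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  q <- (q %||% pwm$q)[c("A", "C", "G", "T")]
  D <- round(pwm$S / eps)
  cur <- 1
  cur_min <- 0
  for (i in seq_len(pwm$w)) {
    d <- D[, i]
    new_min <- cur_min + min(d)
    new_max <- cur_min + (length(cur) - 1L) + max(d)
    new <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      shift <- (cur_min + d[b]) - new_min
      idx <- seq_along(cur) + shift
      new[idx] <- new[idx] + cur * q[b]
    }
    cur <- new
    cur_min <- new_min
  }
  keep <- cur > 0
  data.frame(score = (cur_min + which(keep) - 1) * eps,
             prob = cur[keep])
}

#' Calibrate a PWM match threshold at a tail probability
#'
#' Returns the smallest achievable score t with P(M >= t) <= p under the
#' exact background score distribution, the standard way of converting a
#' match p-value cutoff (0.001 by default) into a score threshold. Because
#' the distribution lives on an `eps` grid while scan scores are exact, the
#' returned threshold is lowered by the maximal rounding error `w * eps / 2`
#' so that every word whose discretized score reaches the grid threshold
#' also passes on the real scale; the admitted boundary band is at most
#' `w * eps` wide. If even the maximal word score has tail probability
#' above p, no word qualifies and `+Inf` is returned with a warning.
#'
#' @param pwm a `pwm`.
#' @param q background frequencies (defaults to the PWM's own `q`).
#' @param p tail probability in (0, 1].
#' @param eps score discretization step.
#' @return scalar score threshold in log-units (possibly `+Inf`).
#' @export
score_threshold <- function(pwm, q = NULL, p = 0.001, eps = 1e-4) {
  assert_scalar_number(p, "p", min = 0, max = 1, strict_min = TRUE)
  dist <- pwm_score_distribution(pwm, q = q, eps = eps)
  tail <- rev(cumsum(rev(dist$prob)))
  ok <- tail <= p + 1e-12
  if (!any(ok)) {
    warning("no word attains tail probability <= p; returning +Inf")
    return(Inf)
  }
  dist$score[which(ok)[1]] - pwm$w * eps / 2
}
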