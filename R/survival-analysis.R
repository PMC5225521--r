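#' Split patients into low/high groups at the median expression
#'
#' Patients at or below the median go to the `low` group, the rest to
#' `high`; the tie rule is deterministic and order-independent. An
#' all-identical input yields a degenerate all-low split with a warning.
#'
#' @param expression numeric per-patient expression values (>= 2 patients);
#'   `NA` values are dropped by callers before splitting.
#' @return factor with levels `low`, `high`, same length/order as input.
#' @export
median_split <- function(expression) {
  if (length(expression) < 2L) stop("need at least 2 patients")
  if (anyNA(expression)) stop("missing expression values must be dropped first")
  m <- median(expression)
  g <- ifelse(expression <= m, "low", "high")
  if (all(g == "low"))
    warning("degenerate median split: all patients in the low group")
  factor(g, levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Computes the standard log-rank statistic (sum of observed-minus-expected
#' events in one group over distinct event times, squared, divided by the
#' summed hypergeometric variance) and a two-sided p-value from the
#' chi-square distribution with one degree of freedom.
#'
#' @param time positive event/censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @param group two-level grouping (factor or character).
#' @return list with `chisq`, `p`, and the totals `observed`, `expected`
#'   for the first group level.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- as.factor(group)
  if (nlevels(group) != 2L || any(tabulate(group, 2L) == 0L))
    stop("exactly two non-empty groups required")
  g1 <- group == levels(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the standard step-up false discovery
#' rate correction (monotone, capped at 1).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Median-split survival screen over a gene panel
#'
#' For each gene, splits the cohort at the median expression, runs the
#' log-rank test between the groups, and adjusts the p-values by
#' Benjamini-Hochberg. Patients with missing expression for a gene are
#' dropped for that gene (count reported in the `n_dropped` column). The
#' worse-prognosis group is the one with more observed than expected
#' deaths.
#'
#' @param expr_matrix genes x patients numeric matrix of expression.
#' @param surv data frame with columns `patient_id`, `time`, `event`
#'   covering the matrix's patients.
#' @return data frame (gene_id, chisq, p, p_adjusted, worse_group,
#'   n_dropped), ordered as the input genes.
#' @export
survival_screen <- function(expr_matrix, surv) {
  stopifnot(all(colnames(expr_matrix) %in% surv$patient_id))
  surv <- surv[match(colnames(expr_matrix), surv$patient_id), ]
  rows <- lapply(rownames(expr_matrix), function(g) {
    e <- expr_matrix[g, ]
    ok <- !is.na(e)
    grp <- median_split(e[ok])
    lr <- logrank_test(surv$time[ok], surv$event[ok], grp)
    worse <- if (lr$observed > lr$expected) "low" else "high"
    data.frame(gene_id = g, chisq = lr$chisq, p = lr$p,
               worse_group = worse, n_dropped = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  out[, c("gene_id", "chisq", "p", "p_adjusted", "worse_group", "n_dropped")]
}
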