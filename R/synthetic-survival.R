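#' Simulate a survival cohort with a median-linked expression effect
#'
#' Draws one continuous expression value per patient, splits the cohort at
#' the median, and samples exponential event times whose hazard in the
#' above-median group is `hazard_ratio` times the baseline. Censoring is
#' applied independently per patient with probability `censor_rate`, at a
#' uniform random fraction of the event time, so the expected censored
#' fraction equals `censor_rate` exactly.
#'
#' @param n_patients cohort size (>= 2).
#' @param hazard_ratio hazard ratio of the high-expression group (> 0); 1
#'   gives a null cohort.
#' @param censor_rate censoring probability in `[0, 1)`.
#' @param seed integer seed (substream-expanded).
#' @param baseline_hazard exponential hazard of the low-expression group,
#'   in events per unit time.
#' @return data frame (patient_id, time, event, expression); `event` is 1
#'   for an observed death, 0 for censoring.
#' @export
generate_survival <- function(n_patients, hazard_ratio, censor_rate = 0,
                              seed = 1L, baseline_hazard = 0.1) {
  assert_scalar_number(n_patients, "n_patients", min = 2)
  if (!is.finite(hazard_ratio) || hazard_ratio <= 0)
    stop("hazard_ratio must be > 0")
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  set.seed(substream_seed(seed, "survival"))

  expression <- rnorm(n_patients)
  high <- expression > median(expression)
  rate <- baseline_hazard * ifelse(high, hazard_ratio, 1)
  time <- rexp(n_patients, rate = rate)
  event <- rep(1L, n_patients)
  if (censor_rate > 0) {
    cens <- runif(n_patients) < censor_rate
    time[cens] <- time[cens] * runif(sum(cens))
    event[cens] <- 0L
  }
  data.frame(patient_id = sprintf("pt%04d", seq_len(n_patients)),
             time = time, event = event, expression = expression,
             stringsAsFactors = FALSE)
}
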