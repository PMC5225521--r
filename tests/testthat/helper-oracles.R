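# Independent oracles: deliberately written without reusing the package's
# code paths, so each check has two routes to the same quantity.

# Brute-force PWM score tail by enumerating all 4^w words. Scores are
# discretized to the same grid (integer multiples of eps) so any residual
# disagreement with the dynamic programme is pure floating-point error.
enum_score_distribution <- function(pwm, q, eps = 1e-4) {
  w <- ncol(pwm$S)
  D <- round(pwm$S / eps)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- integer(nrow(words))
  prob <- numeric(nrow(words)) + 1
  for (i in seq_len(w)) {
    score <- score + D[cbind(words[, i], i)]
    prob <- prob * q[words[, i]]
  }
  agg <- rowsum(prob, score)
  data.frame(score = as.numeric(rownames(agg)) * eps, prob = agg[, 1])
}

enum_tail <- function(dist) {
  data.frame(score = dist$score,
             tail = rev(cumsum(rev(dist$prob))))
}

# Log-rank statistic recomputed from first principles with a different code
# shape (risk tables via outer comparisons, no loop over shared state).
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  at_risk <- outer(time, ts, ">=")                # n x T
  died <- outer(time, ts, "==") & event == 1
  n <- colSums(at_risk); n1 <- colSums(at_risk & g1)
  d <- colSums(died); d1 <- colSums(died & g1)
  E <- d * n1 / n
  V <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  (sum(d1) - sum(E))^2 / sum(V)
}

# Permutation distribution of the log-rank statistic over group relabelings.
perm_logrank_pvalue <- function(time, event, group, B = 2000, seed = 1) {
  obs <- oracle_logrank_chisq(time, event, group)
  set.seed(seed)
  perm <- replicate(B, oracle_logrank_chisq(time, event, sample(group)))
  mean(perm >= obs - 1e-12)
}

# Interval sweep: checks pairwise disjointness of [start, end) intervals
# without interval libraries.
intervals_disjoint <- function(start, end) {
  o <- order(start)
  all(start[o][-1] >= end[o][-length(end)])
}
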