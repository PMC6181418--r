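# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately written as plain loops over the
# textbook formulas, sharing no code with the package internals.

# Two-group log-rank chi-square from the hypergeometric terms at each
# distinct event time (tie-corrected variance).
oracle_logrank2 <- function(time, event, group1) {
  taus <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tau in taus) {
    at_risk <- time >= tau
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(event == 1 & time == tau)
    d1 <- sum(event == 1 & time == tau & group1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Exhaustive minimum-p scan: brute-force log-rank at every admissible
# observed cutoff, returning the argmax cutoff (smallest on ties).
oracle_best_cutpoint <- function(dens, time, event, min_group_frac) {
  n <- length(dens)
  k <- ceiling(min_group_frac * n)
  cands <- sort(unique(dens))
  cands <- cands[vapply(cands, function(v) {
    sum(dens <= v) >= k && sum(dens > v) >= k
  }, logical(1))]
  chis <- vapply(cands, function(v) {
    oracle_logrank2(time, event, dens > v)
  }, numeric(1))
  list(cutoff = cands[which.max(chis)], chi = max(chis),
       candidates = cands, chis = chis)
}

# Literal Benjamini-Hochberg step-up rule: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * ps[i:m] / seq(i, m))
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Cox partial log-likelihood for a single covariate with no tied event
# times, maximized by grid refinement.
oracle_cox1 <- function(x, time, event) {
  loglik <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE)$maximum
}

# Small random right-censored dataset with ties, for oracle comparisons.
random_surv_data <- function(n, two_groups = TRUE) {
  time <- sample(1:8, n, replace = TRUE)          # forces ties
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1
  g <- rbinom(n, 1, 0.5)
  if (two_groups && length(unique(g)) < 2) g[1] <- 1 - g[1]
  list(time = time, event = event, group = g)
}
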