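# Shared fixtures, built in code at test time.

# a tiny two-population panel for low-dimensional mixture checks
tiny_panel <- function() {
  panel_schema("T1", data.frame(
    name = c("FSC-A", "FSC-H", "SSC-A", "M1", "M2"),
    role = c("scatter_a", "scatter_h", "side_scatter",
             "fluorescence", "fluorescence"),
    marker = c(NA, NA, NA, "M1", "M2"),
    stringsAsFactors = FALSE))
}

tiny_populations <- function(mu1 = c(M1 = 1, M2 = 4), mu2 = c(M1 = 4, M2 = 1)) {
  mk <- function(mu, freq) list(
    channel_means = mu,
    channel_sds = c(M1 = 0.3, M2 = 0.3),
    base_frequency = freq,
    scatter_profile = c(fsc = 50000, ssc = 30000))
  list(popA = mk(mu1, 0.5), popB = mk(mu2, 0.5))
}

# small default-panel cohort used by gating tests
small_cohort <- function(n_patients = 6, n_events = 2500, seed = 5, ...) {
  simulate_cohort(cohort_spec(n_patients = n_patients,
                              n_events_per_sample = n_events,
                              seed = seed, ...))
}

# brute-force pairwise-concordance ROC-AUC oracle
auc_oracle <- function(y01, scores) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive Youden scan oracle over every candidate cut
youden_oracle <- function(y01, scores) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
  n1 <- sum(y01); n0 <- sum(1 - y01)
  J <- vapply(cand, function(t)
    sum(scores >= t & y01 == 1) / n1 + sum(scores < t & y01 == 0) / n0 - 1,
    numeric(1))
  max(J)
}

# hand-coded Cox partial likelihood (no ties), for brute-force maximization
cox_partial_loglik <- function(beta, x, times, events) {
  ord <- order(times)
  x <- x[ord]; events <- events[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(x)) {
    if (!events[i]) next
    risk <- i:length(x)
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# full hypergeometric enumeration oracle for a 2x2 Fisher test
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k)
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)),
    numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
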