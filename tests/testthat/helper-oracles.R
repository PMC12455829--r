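# Independent oracles: deliberately written as brute-force/textbook routes,
# kept separate from the package's implementation paths.

# Welch p-value via stats::t.test (the package computes Welch vectorized).
oracle_welch_p <- function(a, b) {
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

# Benjamini-Hochberg step-up, brute force: sort, p * m / rank, cumulative
# minimum from the largest rank down (the package uses stats::p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p for a 2x2 table via the hypergeometric pmf:
# sum of all outcome probabilities not exceeding the observed one.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b          # margin of gene i positive
  n <- c + d
  k <- a + c          # margin of gene j positive
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Poisson-binomial pmf by direct convolution.
oracle_poisson_binomial <- function(probs) {
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

# Independent restatement of the three-stream TF classification rule,
# written per-case rather than vectorized.
oracle_classify_tf <- function(motif, ip, rna) {
  calls <- c(motif, ip, rna)
  a <- sum(calls == "cond_a")
  b <- sum(calls == "cond_b")
  if (a > 0 && b > 0) return("mixed")
  if (motif == "shared_open") {
    if (a + b > 0) return("mixed")
    return("shared")
  }
  if (a >= 2) return("a_specific")
  if (b >= 2) return("b_specific")
  "unassigned"
}

# Exact 2x2 joint odds ratio from cell probabilities.
oracle_odds_ratio <- function(p11, pi, pj) {
  p10 <- pi - p11; p01 <- pj - p11; p00 <- 1 - pi - pj + p11
  (p11 * p00) / (p10 * p01)
}

# Expected accuracy of the classifier under per-stream corruption, by exact
# enumeration over generating patterns and corruption outcomes.
oracle_tf_expected_accuracy <- function(label_mix, noise_rate) {
  motif_vals <- c("cond_a", "cond_b", "shared_open", "none")
  dir_vals <- c("cond_a", "cond_b", "none")
  spec_patterns <- function(d) {
    list(c(d, d, "none"), c(d, "none", d), c("none", d, d), c(d, d, d))
  }
  unassigned_patterns <- list(
    c("none", "none", "none"),
    c("cond_a", "none", "none"), c("cond_b", "none", "none"),
    c("none", "cond_a", "none"), c("none", "cond_b", "none"),
    c("none", "none", "cond_a"), c("none", "none", "cond_b"))
  patterns <- list(
    a_specific = spec_patterns("cond_a"),
    b_specific = spec_patterns("cond_b"),
    shared = list(c("shared_open", "none", "none")),
    unassigned = unassigned_patterns)
  corrupt_prob <- function(from, to, vals) {
    if (from == to) 1 - noise_rate else noise_rate / (length(vals) - 1)
  }
  acc <- 0
  for (lab in names(label_mix)) {
    if (label_mix[[lab]] == 0) next
    pats <- patterns[[lab]]
    p_correct <- 0
    for (pat in pats) {
      for (m in motif_vals) for (i in dir_vals) for (r in dir_vals) {
        pr <- corrupt_prob(pat[1], m, motif_vals) *
          corrupt_prob(pat[2], i, dir_vals) *
          corrupt_prob(pat[3], r, dir_vals)
        if (pr == 0) next
        if (oracle_classify_tf(m, i, r) == lab) p_correct <- p_correct + pr
      }
    }
    acc <- acc + label_mix[[lab]] * p_correct / length(pats)
  }
  acc
}
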