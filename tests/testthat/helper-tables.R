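# Shared generators and brute-force oracles for the test suite.

# a random contingency table with positive total
random_table <- function(q = sample(2:5, 1), max_count = 50) {
  counts <- matrix(sample(0:max_count, q * q, replace = TRUE), q, q)
  if (sum(counts) == 0) counts[1, 1] <- 1L
  contingency_table(counts)
}

# a random strictly positive joint distribution (no zero cells)
random_joint <- function(q = sample(2:5, 1)) {
  probs <- matrix(stats::rexp(q * q) + 1e-6, q, q)
  joint_distribution(probs / sum(probs))
}

# a random probability vector bounded away from degeneracy
random_pv <- function(q = sample(2:5, 1)) {
  p <- stats::rexp(q) + 0.05
  p / sum(p)
}

# a random column-stochastic matrix
random_gamma <- function(q) {
  g <- matrix(stats::rexp(q * q) + 0.05, q, q)
  sweep(g, 2, colSums(g), "/")
}

# brute-force plug-in entropy/MI oracles, written independently of the
# package internals (plain loops, natural log, change of base at the end)
oracle_entropy <- function(p, base) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h / log(base)
}

oracle_mi <- function(probs, base) {
  px <- rowSums(probs)
  py <- colSums(probs)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (probs[i, j] > 0) {
        mi <- mi + probs[i, j] * log(probs[i, j] / (px[i] * py[j]))
      }
    }
  }
  mi / log(base)
}

oracle_ia <- function(counts) {
  probs <- counts / sum(counts)
  oracle_mi(probs, 2) /
    min(oracle_entropy(rowSums(probs), 2), oracle_entropy(colSums(probs), 2))
}

# fixture tables used across files
scenario_tables <- function() agreement_fixtures()[paste0("Scenario", 1:6)]
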