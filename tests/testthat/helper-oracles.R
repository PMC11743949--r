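# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own linear-algebra shortcuts.

# Random hypergraph with n <= n_max vertices and m <= m_max hyperedges.
random_hypergraph <- function(seed, n_max = 8, m_max = 6) {
  withr::with_seed(seed, {
    n <- sample(2:n_max, 1)
    m <- sample(1:m_max, 1)
    edges <- lapply(seq_len(m), function(i) {
      size <- sample(seq_len(n), 1)
      sort(sample(seq_len(n), size))
    })
    hypergraph(n, edges, weights = runif(m, 0.5, 2))
  })
}

# Pairwise-sum form of the smoothness functional over ordered pairs.
brute_smoothness <- function(x, a) {
  n <- nrow(x)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + a[i, j] * sum((x[i, ] - x[j, ])^2)
    }
  }
  total / 4
}

# Double-loop evaluation of one hypergraph convolution restricted to
# hyperedges incident to each vertex.
brute_hyperconv <- function(g, x, p) {
  n <- g$n_vertices
  out <- matrix(0, n, ncol(p$weight))
  for (v in seq_len(n)) {
    acc <- rep(0, ncol(p$weight))
    for (e in seq_along(g$hyperedges)) {
      members <- g$hyperedges[[e]]
      if (!(v %in% members)) next
      inner <- rep(0, ncol(p$weight))
      for (u in members) {
        inner <- inner + as.numeric(t(p$weight) %*% x[u, ])
      }
      acc <- acc + inner / length(members)
    }
    out[v, ] <- acc + p$bias
  }
  wpinjury:::apply_activation(out, p$activation)
}

# Two-tailed Fisher p-value by direct enumeration of the hypergeometric
# support, with the pmf computed from log-factorials (independent of
# dhyper and of the package implementation).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Shortened classifier training protocol for unit tests (same optimizer and
# learning-rate schedule, fewer epochs).
classifier_settings_for_tests <- function(seed) {
  train_settings(optimizer = "sgd", learning_rate = 0.01, max_epochs = 80,
                 patience = 80, seed = seed)
}

# Small deterministic cohort helper for classifier/pattern tests.
tiny_cohort <- function(seed = 1, n = 26, sep = 1.5, rates = NULL, d = 320) {
  generate_cohort(simulation_config(n_athletes = n, n_features = d,
                                    class_separation = sep,
                                    site_rates = rates, seed = seed))
}
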