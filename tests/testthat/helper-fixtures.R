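# Shared fixtures. Everything is generated in code; nothing is read from disk.

# A small phantom configuration that keeps per-test volumes cheap.
small_config <- function(...) {
  phantom_config(volume_shape = c(6L, 64L, 64L), ...)
}

# A compact network for tests that only need a working classifier.
tiny_spec <- function(n_channels = 1L, patch_size = 33L) {
  network_spec(n_conv_layers = 2L, conv_filters = c(4L, 6L), fc_neurons = 8L,
               dropout_rate = 0, n_input_channels = n_channels,
               patch_size = patch_size)
}

# Linearly separable toy patch set: bright (class 1) vs dark (class 0).
toy_patch_set <- function(n = 200L, side = 9L, seed = 3L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  patches <- array(0, c(n, 1L, side, side))
  for (i in seq_len(n)) {
    patches[i, 1L, , ] <- rnorm(side * side,
                                mean = ifelse(labels[i] == 1L, 2, -2), sd = 0.5)
  }
  list(patches = patches, labels = labels)
}

# A deterministic hand-made mixture (valid gmm_model without an EM fit).
manual_gmm <- function(weights, means, variances) {
  structure(list(weights = weights, means = means, variances = variances,
                 K = length(weights), loglik = NA_real_, n = 0L, n_iter = 0L,
                 seed = 0L),
            class = "gmm_model")
}

# Literal double-loop Fisher-vector oracle following the first/second-order
# statistic formulas term by term; independent of encode_case's vectorised path.
fv_oracle <- function(R, gmm) {
  Tn <- nrow(R); nf <- ncol(R); K <- gmm$K
  vals <- numeric(2L * K * nf)
  for (f in seq_len(nf)) {
    for (k in seq_len(K)) {
      G <- 0; H <- 0
      for (t in seq_len(Tn)) {
        x <- R[t, f]
        num <- gmm$weights * stats::dnorm(x, gmm$means, sqrt(gmm$variances))
        gam <- num[k] / sum(num)
        u <- (x - gmm$means[k]) / sqrt(gmm$variances[k])
        G <- G + gam * u
        H <- H + gam * (u^2 - 1)
      }
      vals[(f - 1L) * 2L * K + 0L * K + k] <- G / (Tn * sqrt(gmm$weights[k]))
      vals[(f - 1L) * 2L * K + 1L * K + k] <- H / (Tn * sqrt(2 * gmm$weights[k]))
    }
  }
  vals
}

# Brute-force AUC: concordant positive-negative pairs, half credit for ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
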