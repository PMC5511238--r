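test_that("a one-component fit recovers the closed-form Gaussian MLE", {
  set.seed(5)
  x <- rnorm(500, mean = 2, sd = 3)
  g <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(g$means, mean(x), tolerance = 1e-6)
  expect_equal(g$variances, var(x) * (length(x) - 1) / length(x),
               tolerance = 1e-3)
  expect_equal(g$weights, 1)
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(7)
  x <- c(rnorm(5000, -5, 0.5), rnorm(5000, 5, 0.5))
  g <- fit_gmm(x, K = 2, seed = 9)
  mu <- sort(g$means)
  expect_lt(abs(mu[1] - (-5)), 0.1)
  expect_lt(abs(mu[2] - 5), 0.1)
  expect_true(all(abs(g$weights - 0.5) < 0.05))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_true(all(g$variances > 0))
})

test_that("a mixture fit agrees with an independent EM implementation", {
  library(mclust)  # Mclust dispatches to unexported helpers when attached
  set.seed(11)
  x <- c(rnorm(2000, -1, 0.4), rnorm(3000, 2, 0.8))
  g <- fit_gmm(x, K = 2, seed = 2)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(g$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("degenerate pools are rejected", {
  expect_error(fit_gmm(rep(seq_len(100), 10), K = 64, seed = 1), "distinct")
  expect_error(fit_gmm(rnorm(50), K = 64, seed = 1), "distinct")
})

test_that("posteriors are normalized and follow symmetry", {
  g1 <- manual_gmm(1, 0, 1)
  expect_equal(as.vector(gmm_posterior(g1, c(-3, 0, 7))), c(1, 1, 1))
  gs <- manual_gmm(c(0.5, 0.5), c(-2, 2), c(1, 1))
  expect_equal(as.vector(gmm_posterior(gs, 0)), c(0.5, 0.5))
  set.seed(3)
  g3 <- manual_gmm(c(0.2, 0.5, 0.3), c(-1, 0, 4), c(0.3, 1, 2))
  p <- gmm_posterior(g3, rnorm(50))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("the hand-computed single-response encoding is reproduced", {
  g <- manual_gmm(1, 0, 1)
  raw <- encode_case(matrix(0, 1, 1), g, signed_sqrt = FALSE, l2 = FALSE)
  expect_equal(raw$values, c(0, -1 / sqrt(2)), tolerance = 1e-12)
  post <- encode_case(matrix(0, 1, 1), g)
  expect_equal(post$values, c(0, -1), tolerance = 1e-12)
})

test_that("descriptor indexing is the documented bijection", {
  # 0-based positions: (0,0,0) -> 0; (127,63,1) -> 16383; (106,35,0) -> 13603
  expect_identical(descriptor_index(0, 0, 0) - 1L, 0L)
  expect_identical(descriptor_index(127, 63, 1) - 1L, 16383L)
  expect_identical(descriptor_index(106, 35, 0) - 1L, 13603L)
  expect_error(descriptor_index(128, 0, 0), "out of range")
  expect_error(descriptor_index(0, 64, 0), "out of range")
  for (idx in c(1L, 99L, 16384L)) {
    inv <- descriptor_index_inverse(idx)
    expect_identical(descriptor_index(inv$f, inv$k, inv$order), idx)
  }
})

test_that("encode_case equals a literal double-loop oracle on random instances", {
  set.seed(21)
  for (rep in 1:20) {
    nf <- sample(1:4, 1)
    K <- sample(2:5, 1)
    Tn <- sample(5:100, 1)
    R <- matrix(rnorm(Tn * nf, sd = runif(1, 0.5, 2)), Tn, nf)
    w <- runif(K); w <- w / sum(w)
    g <- manual_gmm(w, rnorm(K), runif(K, 0.2, 2))
    enc <- encode_case(R, g, signed_sqrt = FALSE, l2 = FALSE)
    expect_equal(enc$values, fv_oracle(R, g), tolerance = 1e-8)
  }
})

test_that("descriptors of model-sampled responses vanish as T grows", {
  g <- manual_gmm(c(0.3, 0.7), c(-1, 1.5), c(0.5, 1.2))
  x <- gmm_sample(g, 1e5, seed = 17)
  enc <- encode_case(matrix(x, ncol = 1), g, signed_sqrt = FALSE, l2 = FALSE)
  first_order <- enc$values[seq_len(g$K)]
  expect_lt(mean(abs(first_order)), 0.02)
})

test_that("improved-FV post-processing flags behave as documented", {
  set.seed(2)
  R <- matrix(rnorm(200), 100, 2)
  g <- manual_gmm(c(0.5, 0.5), c(-1, 1), c(1, 1))
  d <- encode_case(R, g)
  expect_equal(sqrt(sum(d$values^2)), 1, tolerance = 1e-12)
  expect_length(d$values, 2 * 2 * 2)
  raw <- encode_case(R, g, signed_sqrt = FALSE, l2 = FALSE)
  expect_equal(sign(d$values), sign(raw$values))
  # permuting responses leaves the descriptor unchanged
  d2 <- encode_case(R[sample(nrow(R)), , drop = FALSE], g)
  expect_equal(d$values, d2$values, tolerance = 1e-12)
  expect_error(encode_case(matrix(0, 0, 1), g), "T = 0")
})
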