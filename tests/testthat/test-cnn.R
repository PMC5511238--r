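test_that("reference and ablation architectures build with the right widths", {
  spec <- network_spec(n_conv_layers = 6L, fc_neurons = 4096L)
  expect_identical(tail(spec$conv_filters, 1L), 128L)
  net <- build_network(spec, seed = 1)
  expect_gt(net$n_params, 1e6)
  last_conv <- Filter(function(l) l$type == "conv", net$layers)
  expect_identical(nrow(last_conv[[length(last_conv)]]$W), 128L)
  rm(net); gc(verbose = FALSE)
  # shallow ablation endpoint
  spec2 <- network_spec(n_conv_layers = 1L, conv_filters = 16L,
                        fc_neurons = 256L)
  net2 <- build_network(spec2, seed = 1)
  expect_s3_class(net2, "dlr_network")
  # receptive field beyond the patch is rejected
  expect_error(network_spec(n_conv_layers = 5L, patch_size = 9L),
               "receptive field")
  expect_error(network_spec(n_conv_layers = 2L, conv_filters = c(4L, 4L, 4L)),
               "length")
})

test_that("forward pass emits two probabilities summing to one", {
  net <- build_network(tiny_spec(patch_size = 9L), seed = 2)
  X <- array(rnorm(9 * 9 * 1 * 5), c(9, 9, 1, 5))
  pr <- dlradiomics:::cnn_predict(net, X)
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("analytic gradients match numeric differentiation in every layer", {
  spec <- network_spec(n_conv_layers = 2L, conv_filters = c(3L, 4L),
                       fc_neurons = 5L, dropout_rate = 0,
                       n_input_channels = 2L, patch_size = 9L)
  net <- build_network(spec, seed = 2)
  set.seed(1)
  X <- array(rnorm(9 * 9 * 2 * 3), c(9, 9, 2, 3))
  y <- c(0, 1, 1)
  g <- dlradiomics:::cnn_batch_grad(net, X, y, train = FALSE)
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    if (is.null(net$layers[[li]]$W)) next
    for (ii in sample(length(net$layers[[li]]$W), 4)) {
      n2 <- net
      n2$layers[[li]]$W[ii] <- n2$layers[[li]]$W[ii] + eps
      lp <- dlradiomics:::cnn_batch_grad(n2, X, y, train = FALSE)$loss
      n2$layers[[li]]$W[ii] <- n2$layers[[li]]$W[ii] - 2 * eps
      lm <- dlradiomics:::cnn_batch_grad(n2, X, y, train = FALSE)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(g$grads[[li]]$dW[ii], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates a linearly separable toy problem", {
  pset <- toy_patch_set()
  spec <- network_spec(n_conv_layers = 1L, conv_filters = 4L, fc_neurons = 8L,
                       dropout_rate = 0, n_input_channels = 1L, patch_size = 9L)
  net <- build_network(spec, seed = 4)
  tr <- train_network(net, pset,
                      sgd = list(learning_rate = 0.01, epochs = 20,
                                 batch_size = 32), seed = 5)
  expect_gte(tail(tr$training_log$accuracy, 1), 0.95)
  expect_true(tr$trained)
  expect_equal(nrow(tr$training_log), 20L)
  # loss decreases overall
  expect_lt(tail(tr$training_log$loss, 1), tr$training_log$loss[1])
})

test_that("training is deterministic for a fixed seed and errors on bad input", {
  pset <- toy_patch_set(n = 60L)
  spec <- network_spec(n_conv_layers = 1L, conv_filters = 3L, fc_neurons = 4L,
                       n_input_channels = 1L, patch_size = 9L)
  net <- build_network(spec, seed = 4)
  t1 <- train_network(net, pset, sgd = list(epochs = 3, batch_size = 16), seed = 9)
  t2 <- train_network(net, pset, sgd = list(epochs = 3, batch_size = 16), seed = 9)
  expect_identical(t1$layers, t2$layers)
  expect_error(train_network(net, list(patches = array(0, c(0, 1, 9, 9)),
                                       labels = integer(0))), "empty")
  one_class <- pset
  one_class$labels <- rep(1L, length(one_class$labels))
  expect_error(train_network(net, one_class), "both classes")
})

test_that("segmentation yields a valid probability map of the input shape", {
  cfg <- small_config()
  vol <- generate_phantom(cfg, 0, 3)
  net <- build_network(tiny_spec(), seed = 1)      # untrained: shape/range only
  res <- segment_volume(net, vol, stride = 8)
  expect_identical(dim(res$probability_map), dim(vol$mask))
  expect_true(all(res$probability_map >= 0 & res$probability_map <= 1))
  expect_identical(dim(res$mask), dim(vol$mask))
  # constant-zero volume: no crash, valid map
  vol0 <- vol
  vol0$intensities[] <- 0
  res0 <- segment_volume(net, vol0, stride = 8)
  expect_true(all(res0$probability_map >= 0 & res0$probability_map <= 1))
  # channel mismatch is refused
  spec2 <- tiny_spec(n_channels = 2L)
  expect_error(segment_volume(build_network(spec2, 1), vol, stride = 8),
               "channel")
})
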