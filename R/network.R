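#' Architecture hyperparameters of the patch-based tumor classifier
#'
#' The pixel-wise classifier follows the patch-CNN family used for glioma
#' segmentation: a stack of 3x3 convolutions with ReLU, two fully connected
#' layers with ReLU and dropout, and a 2-way softmax over the 33x33 patch
#' centred on the voxel being classified. The reference configuration has
#' 6 convolutional layers ending in 128 filters and 4096 fully connected
#' neurons; both are ablation axes. With 3x3 kernels the receptive field is
#' `2 * n_conv_layers + 1` and must not exceed the patch size.
#'
#' @param n_conv_layers number of convolutional layers (1-6 typical).
#' @param conv_filters integer vector of per-layer filter counts, length
#'   `n_conv_layers`; the last entry is the number of deep filters harvested
#'   downstream. Default: `c(64, 64, 128, 128, 128, 128)` for 6 layers,
#'   otherwise 64 per layer with a 128-filter final layer.
#' @param fc_neurons neurons in each of the two fully connected layers.
#' @param dropout_rate dropout fraction after each fully connected layer.
#' @param n_input_channels 1 or 2 image modalities.
#' @param kernel_size convolution side (3).
#' @param patch_size training patch side (33).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_conv_layers = 6L, conv_filters = NULL,
                         fc_neurons = 4096L, dropout_rate = 0.5,
                         n_input_channels = 1L, kernel_size = 3L,
                         patch_size = 33L) {
  n_conv_layers <- as.integer(n_conv_layers)
  if (is.null(conv_filters)) {
    conv_filters <- if (n_conv_layers == 6L) c(64L, 64L, 128L, 128L, 128L, 128L)
    else c(rep(64L, max(0L, n_conv_layers - 1L)), 128L)
  }
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) != n_conv_layers) {
    stop("length(conv_filters) must equal n_conv_layers", call. = FALSE)
  }
  rf <- n_conv_layers * (kernel_size - 1L) + 1L
  if (rf > patch_size) {
    stop(sprintf("receptive field %d exceeds patch size %d", rf, patch_size),
         call. = FALSE)
  }
  stopifnot(fc_neurons >= 1, dropout_rate >= 0, dropout_rate < 1,
            n_input_channels %in% c(1L, 2L))
  structure(list(n_conv_layers = n_conv_layers, conv_filters = conv_filters,
                 fc_neurons = as.integer(fc_neurons),
                 n_fc_layers = 2L, dropout_rate = dropout_rate,
                 n_input_channels = as.integer(n_input_channels),
                 kernel_size = as.integer(kernel_size),
                 patch_size = as.integer(patch_size), n_classes = 2L),
            class = "network_spec")
}

#' Build an (untrained) network from a spec
#'
#' Weights are He-initialised (`sd = sqrt(2 / fan_in)`) for ReLU layers and
#' `sqrt(1 / fan_in)` for the softmax layer, from the given seed.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for the initial weights.
#' @return object of class `dlr_network` with fields `spec`, `layers`,
#'   `n_params`, `seed`, `trained`, `training_log`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel_size
  with_seed(seed, {
    layers <- list()
    cin <- spec$n_input_channels
    side <- spec$patch_size
    for (f in spec$conv_filters) {
      fan_in <- k * k * cin
      layers[[length(layers) + 1L]] <- list(
        type = "conv",
        W = matrix(stats::rnorm(f * fan_in, sd = sqrt(2 / fan_in)), f, fan_in),
        b = rep(0, f))
      cin <- f
      side <- side - (k - 1L)
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    flat <- side * side * cin
    fan <- flat
    for (i in 1:2) {
      layers[[length(layers) + 1L]] <- list(
        type = "fc",
        W = matrix(stats::rnorm(spec$fc_neurons * fan, sd = sqrt(2 / fan)),
                   spec$fc_neurons, fan),
        b = rep(0, spec$fc_neurons))
      fan <- spec$fc_neurons
    }
    layers[[length(layers) + 1L]] <- list(
      type = "out",
      W = matrix(stats::rnorm(2L * fan, sd = sqrt(1 / fan)), 2L, fan),
      b = rep(0, 2L))
    n_params <- sum(vapply(layers, function(l)
      if (is.null(l$W)) 0 else length(l$W) + length(l$b), 0))
    structure(list(spec = spec, layers = layers, n_params = n_params,
                   seed = as.integer(seed), trained = FALSE,
                   training_log = NULL, geom = new.env(parent = emptyenv())),
              class = "dlr_network")
  })
}

#' @export
print.dlr_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<dlr_network> %d conv layers (%s), fc %d x2, %s, %s params\n",
              s$n_conv_layers, paste(s$conv_filters, collapse = ","),
              s$fc_neurons, if (x$trained) "trained" else "untrained",
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Train the pixel-wise tumor classifier by minibatch SGD
#'
#' Cross-entropy loss, stochastic gradient descent with momentum, dropout
#' after each fully connected layer. Deterministic for a fixed seed.
#'
#' @param net an untrained (or previously trained) `dlr_network`.
#' @param patch_set a `patch_set` from [sample_patches()] (or any list with
#'   `patches` `(n, c, h, w)` and 0/1 `labels`), containing both classes.
#' @param sgd list of optimiser settings: `learning_rate` (0.005), `momentum`
#'   (0.9), `batch_size` (128), `epochs` (30).
#' @param seed RNG seed governing shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return the trained network, with a `training_log` data.frame
#'   (epoch, loss, accuracy).
#' @export
train_network <- function(net, patch_set,
                          sgd = list(learning_rate = 0.005, momentum = 0.9,
                                     batch_size = 128L, epochs = 30L),
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "dlr_network"))
  defaults <- list(learning_rate = 0.005, momentum = 0.9,
                   batch_size = 128L, epochs = 30L)
  sgd <- utils::modifyList(defaults, sgd)
  n <- dim(patch_set$patches)[1L]
  if (is.null(n) || n == 0L) stop("patch set is empty", call. = FALSE)
  y <- patch_set$labels
  if (length(unique(y)) < 2L) {
    stop("patch set must contain both classes", call. = FALSE)
  }
  X <- aperm(patch_set$patches, c(3L, 4L, 2L, 1L))    # (h, w, c, n)
  vel <- lapply(net$layers, function(l)
    if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0))
  log_rows <- vector("list", sgd$epochs)
  with_seed(seed, {
    for (ep in seq_len(sgd$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0; nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(n, i + sgd$batch_size - 1L)
        sel <- ord[i:j]
        g <- cnn_batch_grad(net, X[, , , sel, drop = FALSE], y[sel])
        for (li in seq_along(net$layers)) {
          if (is.null(g$grads[[li]])) next
          vel[[li]]$W <- sgd$momentum * vel[[li]]$W -
            sgd$learning_rate * g$grads[[li]]$dW
          vel[[li]]$b <- sgd$momentum * vel[[li]]$b -
            sgd$learning_rate * g$grads[[li]]$db
          net$layers[[li]]$W <- net$layers[[li]]$W + vel[[li]]$W
          net$layers[[li]]$b <- net$layers[[li]]$b + vel[[li]]$b
        }
        tot_loss <- tot_loss + g$loss * length(sel)
        tot_correct <- tot_correct + g$correct
        nb <- nb + 1L
        i <- j + 1L
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = tot_loss / n,
                                   accuracy = tot_correct / n)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep,
                        tot_loss / n, tot_correct / n))
      }
    }
  })
  net$trained <- TRUE
  net$training_log <- do.call(rbind, log_rows)
  net
}

# Replicate-pad a 2-D slice by `half` pixels on every side.
pad_replicate <- function(m, half) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * half) - half, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * half) - half, 1L), ncol(m))
  m[ri, ci]
}

#' Dense tumor-probability inference over a volume
#'
#' Applies the trained patch classifier at every voxel of every axial slice:
#' each voxel's `patch_size` neighbourhood (replicate-padded at the borders)
#' is standardized per channel exactly as during training and classified.
#' With `stride > 1` the classifier is evaluated on a sub-sampled grid and
#' the probability map is up-sampled back to input resolution by bicubic
#' interpolation.
#'
#' @param net a trained `dlr_network`.
#' @param volume a `labeled_volume` (its mask, if any, is ignored).
#' @param stride inference grid spacing in voxels (1 = every voxel).
#' @param chunk patches per forward chunk.
#' @return a `segmentation_result`: list with `probability_map`
#'   (`(z, y, x)` array in `[0, 1]`) and `mask` (binary array from
#'   [postprocess_mask()] at threshold 0.5).
#' @export
segment_volume <- function(net, volume, stride = 1L, chunk = 256L) {
  stopifnot(inherits(net, "dlr_network"), inherits(volume, "labeled_volume"))
  spec <- net$spec
  nch <- dim(volume$intensities)[1L]
  if (nch != spec$n_input_channels) {
    stop(sprintf("volume has %d channel(s) but network expects %d",
                 nch, spec$n_input_channels), call. = FALSE)
  }
  d <- dim(volume$mask)
  ps <- spec$patch_size
  half <- (ps - 1L) %/% 2L
  prob <- array(0, d)
  ys <- seq.int(1L, d[2L], by = stride)
  xs <- seq.int(1L, d[3L], by = stride)
  Hp <- d[2L] + 2L * half
  off <- as.vector(outer(0:(ps - 1L), (0:(ps - 1L)) * Hp, "+"))
  base <- as.vector(outer(ys, (xs - 1L) * Hp, "+"))
  idx1 <- outer(off, base, "+")                      # window indices, 1 channel
  P <- length(base)
  for (z in seq_len(d[1L])) {
    col <- matrix(0, ps * ps * nch, P)
    for (ch in seq_len(nch)) {
      padded <- pad_replicate(volume$intensities[ch, z, , ], half)
      block <- padded[idx1]
      dim(block) <- c(ps * ps, P)
      mu <- colMeans(block)
      sdv <- sqrt(pmax(colMeans(block^2) - mu^2, 0) * (ps * ps) / (ps * ps - 1))
      sdv[sdv < .Machine$double.eps^0.5] <- Inf      # constant window -> zeros
      block <- sweep(sweep(block, 2L, mu), 2L, sdv, "/")
      col[((ch - 1L) * ps * ps + 1L):(ch * ps * ps), ] <- block
    }
    dim(col) <- c(ps, ps, nch, P)
    probs <- cnn_predict(net, col, chunk = chunk)[, 2L]
    pm <- matrix(probs, length(ys), length(xs))
    if (stride > 1L) pm <- resize_bicubic(pm, d[2L], d[3L])
    prob[z, , ] <- pmin(pmax(pm, 0), 1)
  }
  mask <- postprocess_mask(prob)
  structure(list(probability_map = prob, mask = mask),
            class = "segmentation_result")
}

# 4-connected component labelling of a logical matrix; returns integer labels.
label_components4 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- integer(H * W)
  fg <- which(m)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < H] + 1L,
              frontier[frontier > H] - H, frontier[frontier <= H * (W - 1L)] + H)
      nb <- unique(nb[m[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  matrix(lab, H, W)
}

# 3x3x3 box-filter mean of a 3-D array, zero-padded at the borders.
box_mean3 <- function(v) {
  d <- dim(v)
  p <- array(0, d + 2L)
  p[seq_len(d[1L]) + 1L, seq_len(d[2L]) + 1L, seq_len(d[3L]) + 1L] <- v
  s <- p[seq_len(d[1L]), , , drop = FALSE] +
    p[seq_len(d[1L]) + 1L, , , drop = FALSE] +
    p[seq_len(d[1L]) + 2L, , , drop = FALSE]
  s <- s[, seq_len(d[2L]), , drop = FALSE] +
    s[, seq_len(d[2L]) + 1L, , drop = FALSE] +
    s[, seq_len(d[2L]) + 2L, , drop = FALSE]
  s <- s[, , seq_len(d[3L]), drop = FALSE] +
    s[, , seq_len(d[3L]) + 1L, drop = FALSE] +
    s[, , seq_len(d[3L]) + 2L, drop = FALSE]
  array(s, d) / 27
}

#' Morphological post-processing of a tumor probability map
#'
#' Per axial slice, voxels with probability at or above `threshold` are kept
#' and reduced to the largest 4-connected component; the resulting binary
#' stack is then smoothed with a 3x3x3 box filter (zero-padded) and
#' re-thresholded at 0.5, which removes isolated voxels and thin spurs.
#'
#' @param probability_map `(z, y, x)` array with values in `[0, 1]`.
#' @param threshold probability cut for the candidate region (default 0.5).
#' @return binary `(z, y, x)` array.
#' @export
postprocess_mask <- function(probability_map, threshold = 0.5) {
  stopifnot(length(dim(probability_map)) == 3L,
            min(probability_map) >= 0, max(probability_map) <= 1)
  d <- dim(probability_map)
  cand <- array(0, d)
  for (z in seq_len(d[1L])) {
    bin <- probability_map[z, , ] >= threshold
    if (!any(bin)) next
    lab <- label_components4(bin)
    sizes <- tabulate(lab[lab > 0L])
    cand[z, , ] <- (lab == which.max(sizes)) * 1
  }
  (box_mean3(cand) >= 0.5) * 1
}

#' Overlap metrics of a predicted segmentation against ground truth
#'
#' DSC `= 2|P∩T| / (|P|+|T|)`, PPV `= |P∩T| / |P|`, sensitivity
#' `= |P∩T| / |T|`. An empty denominator yields 0 with a warning.
#'
#' @param pred_mask,truth_mask congruent binary arrays.
#' @return named numeric vector `c(dsc, ppv, sensitivity)`.
#' @export
segmentation_metrics <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  p <- sum(pred_mask != 0)
  t <- sum(truth_mask != 0)
  i <- sum(pred_mask != 0 & truth_mask != 0)
  div <- function(num, den, what) {
    if (den == 0) { warning(what, ": empty denominator, returning 0"); 0 }
    else num / den
  }
  c(dsc = div(2 * i, p + t, "dsc"),
    ppv = div(i, p, "ppv"),
    sensitivity = div(i, t, "sensitivity"))
}
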