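# Minimal convolutional-network engine used by the tumor segmentation module.
#
# Layout conventions (column-major, as R stores arrays):
#   activation batch  A[h, w, c, n]
#   conv weights      W[c_out, k*k*c_in]   columns ordered dh-fastest, then dw,
#                                          then input channel (matches the
#                                          column-major flattening of a window)
#   fc weights        W[out, in]           input = as.vector of an (h, w, c) map
#
# Convolutions are "valid" (no padding), stride 1, realised with an im2col
# gather followed by one BLAS matrix product; gradients w.r.t. the input are
# computed as a full convolution with spatially flipped kernels, using the
# same gather machinery. Gather indices depend only on geometry and are cached
# per network.

# Linear gather indices turning X[h, w, c, n] into a (k*k*C) x (P*N) column
# matrix of all valid k x k windows; P windows per image, h-fastest order.
im2col_index <- function(H, W, C, k, N) {
  Hout <- H - k + 1L; Wout <- W - k + 1L
  off <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"),
                         (0:(C - 1L)) * H * W, "+"))
  base <- as.vector(outer(seq_len(Hout), (seq_len(Wout) - 1L) * H, "+"))
  one <- outer(off, base, "+")                       # (k2C, P)
  idx <- outer(as.vector(one), (seq_len(N) - 1L) * (H * W * C), "+")
  dim(idx) <- c(k * k * C, Hout * Wout * N)
  storage.mode(idx) <- "integer"
  idx
}

geom_get <- function(cache, H, W, C, k, N) {
  key <- paste(H, W, C, k, N, sep = "_")
  if (is.null(cache[[key]])) {
    if (length(ls(cache)) > 12L) rm(list = ls(cache), envir = cache)
    cache[[key]] <- im2col_index(H, W, C, k, N)
  }
  cache[[key]]
}

conv_forward <- function(X, Wm, b, k, cache) {
  d <- dim(X)
  Hout <- d[1L] - k + 1L; Wout <- d[2L] - k + 1L
  idx <- geom_get(cache, d[1L], d[2L], d[3L], k, d[4L])
  col <- X[as.vector(idx)]   # vector indexing (a k2C x 4 matrix would be
  dim(col) <- dim(idx)       # misread as coordinate rows)
  Y <- Wm %*% col + b                                # (Cout, P*N)
  Y <- array(Y, c(nrow(Wm), Hout, Wout, d[4L]))
  list(out = aperm(Y, c(2L, 3L, 1L, 4L)), col = col)
}

# Spatially flipped, channel-transposed weights for the input gradient.
conv_flip_weights <- function(Wm, k, Cin) {
  Cout <- nrow(Wm)
  A <- array(t(Wm), c(k, k, Cin, Cout))
  Af <- A[k:1, k:1, , , drop = FALSE]
  B <- aperm(Af, c(1L, 2L, 4L, 3L))                  # (k, k, Cout, Cin)
  t(matrix(B, k * k * Cout, Cin))                    # (Cin, k2*Cout)
}

conv_backward <- function(dZ, col, Wm, k, in_dim, cache, need_dx = TRUE) {
  Cout <- nrow(Wm)
  dY <- aperm(dZ, c(3L, 1L, 2L, 4L))
  dim(dY) <- c(Cout, length(dY) / Cout)
  dW <- tcrossprod(dY, col)
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    H <- in_dim[1L]; W <- in_dim[2L]; Cin <- in_dim[3L]; N <- in_dim[4L]
    Hout <- H - k + 1L; Wout <- W - k + 1L
    pad <- k - 1L
    dPad <- array(0, c(Hout + 2L * pad, Wout + 2L * pad, Cout, N))
    dPad[(pad + 1L):(pad + Hout), (pad + 1L):(pad + Wout), , ] <- dZ
    idx <- geom_get(cache, Hout + 2L * pad, Wout + 2L * pad, Cout, k, N)
    colb <- dPad[as.vector(idx)]
    dim(colb) <- dim(idx)
    dXm <- conv_flip_weights(Wm, k, Cin) %*% colb    # (Cin, H*W*N)
    dX <- aperm(array(dXm, c(Cin, H, W, N)), c(2L, 3L, 1L, 4L))
  }
  list(dW = dW, db = db, dX = dX)
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

as_flat <- function(A) {
  if (is.matrix(A)) return(A)
  d <- dim(A)
  dim(A) <- c(prod(d[1:3]), d[4L])
  A
}

# Full forward pass. X: (h, w, c, n). Returns class probabilities (2 x n) and,
# when `keep`, the per-layer intermediates needed for backprop. Dropout is
# "inverted": activations are rescaled by 1/(1-rate) at train time so the
# test-time pass is the identity.
cnn_forward <- function(net, X, train = FALSE, keep = FALSE) {
  k <- net$spec$kernel_size
  rate <- net$spec$dropout_rate
  caches <- if (keep) vector("list", length(net$layers))
  A <- X
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      cf <- conv_forward(A, layer$W, layer$b, k, net$geom)
      gate <- cf$out > 0
      if (keep) caches[[li]] <- list(col = cf$col, gate = gate,
                                     in_dim = dim(A))
      A <- cf$out * gate
    } else if (layer$type == "flatten") {
      if (keep) caches[[li]] <- list(in_dim = dim(A))
      A <- as_flat(A)
    } else if (layer$type == "fc") {
      Ain <- A
      Z <- layer$W %*% Ain + layer$b
      gate <- Z > 0
      A <- Z * gate
      mask <- NULL
      if (train && rate > 0) {
        mask <- (stats::runif(length(A)) >= rate) / (1 - rate)
        dim(mask) <- dim(A)
        A <- A * mask
      }
      if (keep) caches[[li]] <- list(Ain = Ain, gate = gate, mask = mask)
    } else if (layer$type == "out") {
      Ain <- A
      A <- softmax_cols(layer$W %*% Ain + layer$b)
      if (keep) caches[[li]] <- list(Ain = Ain)
    }
  }
  list(probs = A, caches = caches)
}

# Cross-entropy loss and parameter gradients for one minibatch.
# y is a 0/1 vector giving the class of each patch.
cnn_batch_grad <- function(net, X, y, train = TRUE) {
  fw <- cnn_forward(net, X, train = train, keep = TRUE)
  P <- fw$probs
  n <- ncol(P)
  Y1 <- rbind(`0` = 1 - y, `1` = y)
  loss <- -mean(colSums(Y1 * log(P + 1e-12)))
  correct <- sum((P[2L, ] > 0.5) == (y == 1))
  grads <- vector("list", length(net$layers))
  k <- net$spec$kernel_size
  dA <- NULL
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    cc <- fw$caches[[li]]
    if (layer$type == "out") {
      dZ <- (P - Y1) / n
      grads[[li]] <- list(dW = tcrossprod(dZ, cc$Ain), db = rowSums(dZ))
      dA <- crossprod(layer$W, dZ)
    } else if (layer$type == "fc") {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dZ <- dA * cc$gate
      grads[[li]] <- list(dW = tcrossprod(dZ, cc$Ain), db = rowSums(dZ))
      dA <- crossprod(layer$W, dZ)
    } else if (layer$type == "flatten") {
      dim(dA) <- cc$in_dim
    } else if (layer$type == "conv") {
      dZ <- dA * cc$gate
      cb <- conv_backward(dZ, cc$col, layer$W, k, cc$in_dim, net$geom,
                          need_dx = li > 1L)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dX
    }
  }
  list(loss = loss, grads = grads, correct = correct)
}

# Class-probability prediction for a (possibly large) patch batch, chunked to
# bound the im2col working set. Returns an n x 2 matrix (columns: class 0, 1).
cnn_predict <- function(net, X, chunk = 256L) {
  n <- dim(X)[4L]
  out <- matrix(0, n, 2L)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[i:j, ] <- t(cnn_forward(net, X[, , , i:j, drop = FALSE])$probs)
    i <- j + 1L
  }
  out
}

# Forward through the convolutional stack only; returns the post-ReLU feature
# maps of the last convolutional layer, (h', w', n_filters). Input is one
# image (h, w, c) or (h, w). Used for deep-feature extraction.
cnn_conv_features <- function(net, img) {
  if (length(dim(img)) < 3L || is.null(dim(img))) {
    dim(img) <- c(dim(img) %||% length(img), 1L)
  }
  A <- array(img, c(dim(img), 1L))
  k <- net$spec$kernel_size
  for (layer in net$layers) {
    if (layer$type != "conv") break
    Z <- conv_forward(A, layer$W, layer$b, k, net$geom)$out
    A <- Z * (Z > 0)
  }
  array(A, dim(A)[1:3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
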