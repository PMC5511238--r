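#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Draw `n` child seeds from a parent seed; values stay within 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# FNV-1a over the serialized text of an R object; used only for log provenance.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Keys cubic convolution kernel (a = -0.5), the classic bicubic weight.
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# 1-D cubic interpolation matrix mapping n_in samples to n_out samples.
# Rows are renormalised so constants are reproduced exactly at the borders.
cubic_interp_matrix <- function(n_in, n_out) {
  if (n_in == 1L) return(matrix(1, n_out, 1L))
  # align centres: output pixel i maps to input coordinate (i - .5) * s + .5
  s <- n_in / n_out
  centres <- (seq_len(n_out) - 0.5) * s + 0.5
  W <- matrix(0, n_out, n_in)
  base <- floor(centres)
  for (off in -1:2) {
    idx <- base + off
    w <- cubic_kernel(centres - idx)
    idx <- pmin(pmax(idx, 1L), n_in)  # clamp at borders
    for (i in seq_len(n_out)) {
      W[i, idx[i]] <- W[i, idx[i]] + w[i]
    }
  }
  W / rowSums(W)
}

#' Resize a 2-D image (or multi-channel image) by bicubic interpolation
#'
#' Separable Keys cubic convolution with border clamping, the standard
#' "bicubic" resampler used for scale-space re-sampling and for up-sampling
#' strided probability maps back to input resolution.
#'
#' @param img matrix, or 3-D array `(h, w, channels)`.
#' @param out_h,out_w target spatial size in pixels.
#' @return object of the same rank as `img` with spatial size `out_h x out_w`.
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  f <- function(m) {
    Wr <- cubic_interp_matrix(nrow(m), out_h)
    Wc <- cubic_interp_matrix(ncol(m), out_w)
    Wr %*% m %*% t(Wc)
  }
  if (is.matrix(img)) return(f(img))
  stopifnot(length(dim(img)) == 3L)
  out <- array(0, c(out_h, out_w, dim(img)[3L]))
  for (c in seq_len(dim(img)[3L])) out[, , c] <- f(img[, , c])
  out
}

# Smooth a 3-D array along one axis with a row-normalised Gaussian weight
# matrix (truncated at 3 sigma; weights renormalised so borders keep scale).
gaussian_axis_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  W <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  W[abs(outer(idx, idx, "-")) > ceiling(3 * sigma)] <- 0
  W / rowSums(W)
}

# Separable Gaussian smoothing of a 3-D (z, y, x) array.
gaussian_smooth3d <- function(vol, sigma) {
  d <- dim(vol)
  Wz <- gaussian_axis_matrix(d[1L], sigma)
  Wy <- gaussian_axis_matrix(d[2L], sigma)
  Wx <- gaussian_axis_matrix(d[3L], sigma)
  # z axis: treat as matrix (z, y*x)
  vol <- array(Wz %*% matrix(vol, d[1L], d[2L] * d[3L]), d)
  # y axis
  vol <- aperm(vol, c(2L, 1L, 3L))
  vol <- array(Wy %*% matrix(vol, d[2L], d[1L] * d[3L]), c(d[2L], d[1L], d[3L]))
  vol <- aperm(vol, c(2L, 1L, 3L))
  # x axis
  vol <- aperm(vol, c(3L, 2L, 1L))
  vol <- array(Wx %*% matrix(vol, d[3L], d[2L] * d[1L]), c(d[3L], d[2L], d[1L]))
  aperm(vol, c(3L, 2L, 1L))
}
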