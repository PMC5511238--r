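#' Standardize a patch per channel
#'
#' Removes the per-channel mean and scales to unit (sample) variance,
#' independently for every channel of the patch. A channel with (numerically)
#' zero variance cannot be standardized: a condition of class
#' `dlr_degenerate_patch` is raised so the caller can drop and log the patch.
#'
#' @param patch array `(channel, h, w)` or a plain matrix (single channel).
#' @return patch of the same shape, each channel with mean 0 and variance 1.
#' @export
normalize_patch <- function(patch) {
  single <- is.matrix(patch)
  if (single) patch <- array(patch, c(1L, dim(patch)))
  stopifnot(length(dim(patch)) == 3L)
  for (ch in seq_len(dim(patch)[1L])) {
    v <- patch[ch, , ]
    s <- stats::sd(v)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      stop(structure(class = c("dlr_degenerate_patch", "error", "condition"),
                     list(message = sprintf("constant channel %d: patch cannot be standardized", ch),
                          call = sys.call(-1))))
    }
    patch[ch, , ] <- (v - mean(v)) / s
  }
  if (single) patch[1L, , ] else patch
}

# Eligible patch centres of one volume: full patch support inside the slice.
eligible_centers <- function(volume, half) {
  d <- dim(volume$mask)
  ys <- (half + 1L):(d[2L] - half)
  xs <- (half + 1L):(d[3L] - half)
  if (length(ys) < 1L || length(xs) < 1L) {
    return(list(tumor = integer(0), bg = integer(0), dim = d))
  }
  sub <- volume$mask[, ys, xs, drop = FALSE]
  grid <- expand.grid(z = seq_len(d[1L]), y = ys, x = xs)
  is_tumor <- as.vector(sub) != 0
  list(tumor = which(is_tumor), bg = which(!is_tumor), grid = grid, dim = d)
}

# Proportional allocation of `total` draws over `avail` counts, capped by
# availability; remainders assigned by largest fractional part (ties by index).
allocate_proportional <- function(total, avail) {
  alloc <- integer(length(avail))
  remaining <- total
  active <- avail > 0
  while (remaining > 0 && any(active & (alloc < avail))) {
    w <- ifelse(active, pmax(avail - alloc, 0), 0)
    if (sum(w) == 0) break
    share <- remaining * w / sum(w)
    add <- pmin(floor(share), avail - alloc)
    rem <- remaining - sum(add)
    if (rem > 0) {
      frac <- share - floor(share)
      frac[avail - alloc - add <= 0] <- -1
      ord <- order(-frac, seq_along(frac))
      k <- min(rem, sum(frac >= 0))
      if (k > 0) add[ord[seq_len(k)]] <- add[ord[seq_len(k)]] + 1L
    }
    if (sum(add) == 0) break
    alloc <- alloc + add
    remaining <- total - sum(alloc)
  }
  alloc
}

#' Sample training patches with an unbalanced tumor/background mix
#'
#' Draws `round(n_total * tumor_fraction)` patches whose centre voxel is
#' tumor and the remainder with non-tumor centres (the reference protocol
#' uses ~40% tumor patches). Centres are drawn uniformly without replacement
#' within the region where the full `patch_size x patch_size` support fits in
#' the axial slice, stratified across cases proportionally to each case's
#' eligible-voxel count. Every patch is standardized per channel; degenerate
#' (constant-channel) patches are dropped with a message.
#'
#' @param volumes list of `labeled_volume`s.
#' @param n_total total number of patches requested.
#' @param tumor_fraction fraction of patches with tumor-class centres.
#' @param patch_size odd patch side length (default 33).
#' @param seed RNG seed.
#' @return a `patch_set`: list with `patches` (array `(n, channel,
#'   patch_size, patch_size)`), `labels` (0/1 vector), `centers`
#'   (data.frame `case_id, z, y, x`).
#' @export
sample_patches <- function(volumes, n_total, tumor_fraction = 0.4,
                           patch_size = 33L, seed = 1L) {
  stopifnot(n_total >= 1, patch_size %% 2L == 1L,
            tumor_fraction >= 0, tumor_fraction <= 1)
  half <- (patch_size - 1L) %/% 2L
  elig <- lapply(volumes, eligible_centers, half = half)
  n_tumor_avail <- vapply(elig, function(e) length(e$tumor), 1L)
  n_bg_avail <- vapply(elig, function(e) length(e$bg), 1L)
  empty_tumor <- n_tumor_avail == 0
  if (any(empty_tumor)) {
    warning(sprintf("%d case(s) with no eligible tumor centres skipped for tumor sampling",
                    sum(empty_tumor)))
  }
  if (all(n_tumor_avail + n_bg_avail == 0)) {
    stop("no case has any eligible patch centre", call. = FALSE)
  }
  n_tumor <- round(n_total * tumor_fraction)
  n_bg <- n_total - n_tumor
  alloc_t <- allocate_proportional(n_tumor, n_tumor_avail)
  alloc_b <- allocate_proportional(n_bg, n_bg_avail)

  with_seed(seed, {
    out_patches <- list(); out_labels <- integer(0); out_centers <- list()
    n_dropped <- 0L
    for (i in seq_along(volumes)) {
      v <- volumes[[i]]; e <- elig[[i]]
      picks <- c(if (alloc_t[i] > 0) sample(e$tumor, alloc_t[i]) else integer(0),
                 if (alloc_b[i] > 0) sample(e$bg, alloc_b[i]) else integer(0))
      labs <- c(rep(1L, alloc_t[i]), rep(0L, alloc_b[i]))
      for (j in seq_along(picks)) {
        g <- e$grid[picks[j], ]
        p <- v$intensities[, g$z, (g$y - half):(g$y + half),
                           (g$x - half):(g$x + half), drop = FALSE]
        p <- array(p, dim(p)[-2L])
        p <- tryCatch(normalize_patch(p), dlr_degenerate_patch = function(c) NULL)
        if (is.null(p)) { n_dropped <- n_dropped + 1L; next }
        out_patches[[length(out_patches) + 1L]] <- p
        out_labels <- c(out_labels, labs[j])
        out_centers[[length(out_centers) + 1L]] <-
          data.frame(case_id = v$case_id, z = g$z, y = g$y, x = g$x,
                     stringsAsFactors = FALSE)
      }
    }
    if (n_dropped > 0) message(n_dropped, " degenerate patch(es) dropped")
    if (!length(out_patches)) stop("no usable patches sampled", call. = FALSE)
    n <- length(out_patches)
    nch <- dim(out_patches[[1L]])[1L]
    patches <- array(0, c(n, nch, patch_size, patch_size))
    for (k in seq_len(n)) patches[k, , , ] <- out_patches[[k]]
    structure(list(patches = patches, labels = out_labels,
                   centers = do.call(rbind, out_centers),
                   patch_size = as.integer(patch_size)),
              class = "patch_set")
  })
}
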