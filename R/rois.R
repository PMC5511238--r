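#' Geometric scale ratios spanning a range
#'
#' `n` ratios geometrically spaced between the two endpoints (both included),
#' so successive quotients are constant: `(hi/lo)^(1/(n-1))`.
#'
#' @param n number of scales (default 10).
#' @param range numeric(2) increasing, default `c(0.5, 2)`.
#' @return numeric vector of length `n`.
#' @export
scale_ratios <- function(n = 10L, range = c(0.5, 2.0)) {
  stopifnot(n >= 1, range[1L] < range[2L])
  if (n == 1L) return(range[1L])
  exp(seq(log(range[1L]), log(range[2L]), length.out = n))
}

#' Multi-scale tumor ROI images for deep-feature extraction
#'
#' For every axial slice intersecting the mask: voxels outside the mask are
#' zeroed, the mask bounding box is cropped (zero-padded symmetrically up to
#' `min_input` if smaller), and the crop is resampled by each scale ratio
#' with bicubic interpolation. Ratios are geometrically spaced over
#' `scale_range`, endpoints included. A (slice, scale) combination whose
#' resampled image would be smaller than `min_input` is skipped with a
#' warning.
#'
#' @param volume a `labeled_volume`.
#' @param mask binary `(z, y, x)` array; defaults to the volume's own
#'   (ground-truth) mask, but a predicted mask can be supplied for the fully
#'   automatic mode.
#' @param n_scales number of scales (default 10).
#' @param scale_range ratio range, default `c(0.5, 2)`.
#' @param min_input smallest image side the consuming network accepts (its
#'   convolutional receptive field, `2 * n_conv_layers + 1`).
#' @return a `scaled_roi_set`: list with `slices` (each: `z`, list `images`
#'   of `(h, w, channel)` arrays, one per retained scale, and the retained
#'   `ratios`), `ratios`, `min_input`.
#' @export
multiscale_rois <- function(volume, mask = volume$mask, n_scales = 10L,
                            scale_range = c(0.5, 2.0), min_input = 13L) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (sum(mask != 0) == 0) stop("mask is empty", call. = FALSE)
  ratios <- scale_ratios(n_scales, scale_range)
  d <- dim(mask)
  nch <- dim(volume$intensities)[1L]
  slices <- list()
  n_skipped <- 0L
  for (z in seq_len(d[1L])) {
    ms <- mask[z, , ] != 0
    if (!any(ms)) next
    rr <- range(which(rowSums(ms) > 0))
    cr <- range(which(colSums(ms) > 0))
    h <- rr[2L] - rr[1L] + 1L
    w <- cr[2L] - cr[1L] + 1L
    crop <- array(0, c(max(h, min_input), max(w, min_input), nch))
    r0 <- max(0L, (min_input - h) %/% 2L)
    c0 <- max(0L, (min_input - w) %/% 2L)
    for (ch in seq_len(nch)) {
      sl <- volume$intensities[ch, z, , ] * ms
      crop[r0 + seq_len(h), c0 + seq_len(w), ch] <- sl[rr[1L]:rr[2L], cr[1L]:cr[2L]]
    }
    images <- list(); kept <- numeric(0)
    for (r in ratios) {
      oh <- round(nrow(crop) * r)
      ow <- round(ncol(crop) * r)
      if (oh < min_input || ow < min_input) { n_skipped <- n_skipped + 1L; next }
      images[[length(images) + 1L]] <- resize_bicubic(crop, oh, ow)
      kept <- c(kept, r)
    }
    if (length(images)) {
      slices[[length(slices) + 1L]] <- list(z = z, images = images, ratios = kept)
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d (slice, scale) image(s) below the %d-pixel minimum were skipped",
                    n_skipped, min_input))
  }
  if (!length(slices)) stop("all (slice, scale) images were skipped", call. = FALSE)
  structure(list(slices = slices, ratios = ratios,
                 min_input = as.integer(min_input),
                 case_id = volume$case_id),
            class = "scaled_roi_set")
}

#' Pool last-convolutional-layer filter responses over all ROI images
#'
#' Each scaled ROI image (standardized per channel, like every network input)
#' is forwarded through the convolutional stack; the post-ReLU feature maps
#' of the last convolutional layer are flattened per filter and appended in a
#' fixed order: slice-major, then scale, then column-major raster within the
#' map. All filters share the spatial grid, so every filter yields the same
#' number `T` of scalar responses.
#'
#' @param net a `dlr_network` (training state does not gate extraction).
#' @param roi_set a `scaled_roi_set` from [multiscale_rois()].
#' @return a `filter_response_set`: list with `case_id`, `responses`
#'   (`T x F` matrix), `n_filters`, `n_responses`.
#' @export
extract_filter_responses <- function(net, roi_set) {
  stopifnot(inherits(net, "dlr_network"), inherits(roi_set, "scaled_roi_set"))
  if (!length(roi_set$slices)) stop("roi_set is empty", call. = FALSE)
  nf <- utils::tail(net$spec$conv_filters, 1L)
  blocks <- list()
  for (sl in roi_set$slices) {
    for (img in sl$images) {
      for (ch in seq_len(dim(img)[3L])) {
        v <- img[, , ch]
        s <- stats::sd(v)
        img[, , ch] <- if (s > .Machine$double.eps^0.5) (v - mean(v)) / s else v * 0
      }
      fm <- cnn_conv_features(net, img)              # (h', w', F)
      blocks[[length(blocks) + 1L]] <- matrix(fm, ncol = nf)
    }
  }
  responses <- do.call(rbind, blocks)
  structure(list(case_id = roi_set$case_id %||% NA_character_,
                 responses = responses, n_filters = nf,
                 n_responses = nrow(responses)),
            class = "filter_response_set")
}
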