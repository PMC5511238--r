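#' Configuration for the multi-modal MR phantom generator
#'
#' The phantom emulates the minimal structure the pipeline needs from a
#' co-registered, skull-stripped low-grade-glioma study: one or two intensity
#' channels, an ellipsoidal tumor brighter than background, an internal tumor
#' texture whose spatial correlation length differs between the two phenotype
#' classes (class 0 smoother than class 1, mirroring the observation that
#' wild-type lesions look more internally complicated than mutants), and
#' additive Gaussian acquisition noise.
#'
#' @param volume_shape integer(3), voxels per axis in `(z, y, x)` order.
#' @param n_channels 1 (single modality) or 2 (e.g. T2-FLAIR + T1-contrast).
#' @param tumor_radius_range numeric(2), min/max in-plane semi-axis in voxels.
#'   Must leave a margin of at least one patch half-width (16 voxels) plus the
#'   2-voxel centre jitter inside the slice.
#' @param tumor_contrast intensity offset of tumor over background.
#' @param texture_corr_length numeric(2), Gaussian correlation length (voxels)
#'   of the internal tumor texture for class 0 and class 1; class 0 must be
#'   the smoother (larger) one.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param background_level baseline intensity outside the tumor.
#' @param seed default seed used by [generate_cohort()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(8L, 64L, 64L),
                           n_channels = 1L,
                           tumor_radius_range = c(8, 13),
                           tumor_contrast = 3,
                           texture_corr_length = c(4, 1.2),
                           noise_sd = 0.5,
                           background_level = 0,
                           seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1))
  if (!n_channels %in% c(1L, 2L)) stop("n_channels must be 1 or 2", call. = FALSE)
  stopifnot(length(tumor_radius_range) == 2L,
            tumor_radius_range[1L] <= tumor_radius_range[2L],
            tumor_radius_range[1L] >= 1)
  if (any(texture_corr_length <= 0)) {
    stop("texture_corr_length must be strictly positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  half_patch <- 16L
  jitter <- 2L
  in_plane <- min(volume_shape[2L], volume_shape[3L])
  if (tumor_radius_range[2L] + half_patch + jitter > floor(in_plane / 2)) {
    stop("tumor_radius_range incompatible with volume_shape: ",
         "tumor must fit with a margin of one patch half-width", call. = FALSE)
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 n_channels = as.integer(n_channels),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 tumor_contrast = tumor_contrast,
                 texture_corr_length = as.numeric(texture_corr_length),
                 noise_sd = noise_sd,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

new_labeled_volume <- function(intensities, mask, label, case_id,
                               diagnosis_time = NA_integer_) {
  stopifnot(length(dim(intensities)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(intensities)[-1L] == dim(mask))) {
    stop("mask and intensities are not spatially congruent", call. = FALSE)
  }
  if (sum(mask) < 1) stop("mask must contain at least one foreground voxel",
                          call. = FALSE)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  structure(list(intensities = intensities, mask = mask,
                 label = as.integer(label), case_id = as.character(case_id),
                 diagnosis_time = as.integer(diagnosis_time)),
            class = "labeled_volume")
}

#' Generate one phantom volume with a labelled tumor
#'
#' Builds an ellipsoidal tumor (analytic ground-truth mask) whose interior
#' carries a unit-variance Gaussian random texture smoothed with an isotropic
#' Gaussian kernel of class-dependent correlation length, on top of a constant
#' background, with i.i.d. Gaussian noise everywhere.
#'
#' @param config a [phantom_config()].
#' @param label phenotype class, 0 or 1.
#' @param seed integer seed; identical `(config, label, seed)` reproduce the
#'   volume bit for bit.
#' @param case_id,diagnosis_time case metadata.
#' @return a `labeled_volume` with fields `intensities` (array
#'   `(channel, z, y, x)`), `mask` (`(z, y, x)` binary), `label`, `case_id`,
#'   `diagnosis_time`.
#' @export
generate_phantom <- function(config, label, seed,
                             case_id = "case_000", diagnosis_time = NA) {
  stopifnot(inherits(config, "phantom_config"))
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  d <- config$volume_shape
  with_seed(seed, {
    nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
    ry <- stats::runif(1L, config$tumor_radius_range[1L], config$tumor_radius_range[2L])
    rx <- stats::runif(1L, config$tumor_radius_range[1L], config$tumor_radius_range[2L])
    rz <- max(1, floor(nz / 2) - 1)
    cz <- (nz + 1) / 2
    cy <- (ny + 1) / 2 + stats::runif(1L, -2, 2)
    cx <- (nx + 1) / 2 + stats::runif(1L, -2, 2)
    zz <- ((seq_len(nz) - cz) / rz)^2
    yy <- ((seq_len(ny) - cy) / ry)^2
    xx <- ((seq_len(nx) - cx) / rx)^2
    mask <- array(outer(outer(zz, yy, "+"), xx, "+") <= 1, c(nz, ny, nx))
    storage.mode(mask) <- "double"
    sigma <- config$texture_corr_length[label + 1L]
    intens <- array(0, c(config$n_channels, nz, ny, nx))
    for (ch in seq_len(config$n_channels)) {
      tex <- gaussian_smooth3d(array(stats::rnorm(nz * ny * nx), c(nz, ny, nx)),
                               sigma)
      s <- stats::sd(tex)
      if (s > 0) tex <- tex / s  # fixed unit variance regardless of smoothing
      noise <- if (config$noise_sd > 0) {
        array(stats::rnorm(nz * ny * nx, sd = config$noise_sd), c(nz, ny, nx))
      } else 0
      intens[ch, , , ] <- config$background_level +
        mask * (config$tumor_contrast + tex) + noise
    }
    new_labeled_volume(intens, mask, label, case_id, diagnosis_time)
  })
}

#' Generate a balanced two-class phantom cohort
#'
#' Cases alternate between the two phenotype classes; `diagnosis_time` equals
#' the case index, so a time-based train/test split is well defined and
#' deterministic.
#'
#' @param n_per_class cases per phenotype class (>= 1).
#' @param config a [phantom_config()].
#' @param seed cohort seed; per-case seeds are derived from it.
#' @return a `phantom_cohort`: list with `volumes` (list of `labeled_volume`)
#'   and `manifest` (data.frame `case_id, label, diagnosis_time`).
#' @export
generate_cohort <- function(n_per_class, config = phantom_config(),
                            seed = config$seed) {
  stopifnot(n_per_class >= 1)
  n <- 2L * as.integer(n_per_class)
  seeds <- derive_seeds(seed, n)
  labels <- rep(c(0L, 1L), length.out = n)
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    volumes[[i]] <- generate_phantom(config, labels[i], seeds[i],
                                     case_id = sprintf("case_%03d", i),
                                     diagnosis_time = i)
  }
  manifest <- data.frame(case_id = vapply(volumes, `[[`, "", "case_id"),
                         label = labels,
                         diagnosis_time = seq_len(n),
                         stringsAsFactors = FALSE)
  structure(list(volumes = volumes, manifest = manifest, config = config),
            class = "phantom_cohort")
}

#' In-mask high-frequency energy of a labelled volume
#'
#' Mean squared first difference of the intensities along y and x restricted
#' to voxel pairs inside the tumor mask. This is the summary statistic that
#' separates the two texture classes: a shorter correlation length yields
#' strictly more high-frequency energy.
#'
#' @param volume a `labeled_volume`.
#' @param channel which channel to measure.
#' @return scalar energy.
#' @export
mask_highfreq_energy <- function(volume, channel = 1L) {
  stopifnot(inherits(volume, "labeled_volume"))
  v <- volume$intensities[channel, , , ]
  m <- volume$mask
  d <- dim(m)
  dy <- (v[, -1L, , drop = FALSE] - v[, -d[2L], , drop = FALSE])^2
  my <- m[, -1L, , drop = FALSE] * m[, -d[2L], , drop = FALSE]
  dx <- (v[, , -1L, drop = FALSE] - v[, , -d[3L], drop = FALSE])^2
  mx <- m[, , -1L, drop = FALSE] * m[, , -d[3L], drop = FALSE]
  (sum(dy * my) + sum(dx * mx)) / max(1, sum(my) + sum(mx))
}
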