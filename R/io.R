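#' Write a phantom cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Each channel and the mask are written as gzipped NIfTI (spatial order is
#' converted from the internal `(z, y, x)` convention to NIfTI `(x, y, z)`).
#' The manifest has columns `case_id,label,diagnosis_time,channel_paths,
#' mask_path`; multiple channel paths are separated by `;` and stored relative
#' to the manifest directory.
#'
#' @param cohort a `phantom_cohort` (or plain list of `labeled_volume`s).
#' @param dir output directory, created if missing.
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  volumes <- if (inherits(cohort, "phantom_cohort")) cohort$volumes else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(volumes, function(v) {
    nch <- dim(v$intensities)[1L]
    ch_paths <- character(nch)
    for (ch in seq_len(nch)) {
      ch_paths[ch] <- sprintf("%s_ch%d.nii.gz", v$case_id, ch)
      RNifti::writeNifti(aperm(v$intensities[ch, , , , drop = FALSE][1, , , ],
                               c(3L, 2L, 1L)),
                         file.path(dir, ch_paths[ch]))
    }
    mask_path <- sprintf("%s_mask.nii.gz", v$case_id)
    RNifti::writeNifti(aperm(v$mask, c(3L, 2L, 1L)), file.path(dir, mask_path))
    data.frame(case_id = v$case_id, label = v$label,
               diagnosis_time = v$diagnosis_time,
               channel_paths = paste(ch_paths, collapse = ";"),
               mask_path = mask_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

read_nifti_zyx <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  aperm(arr, c(3L, 2L, 1L))
}

#' Load a cohort from a manifest CSV
#'
#' Validates the manifest (unique case ids, labels in \{0, 1\}, referenced
#' files present) and reassembles each case into a `labeled_volume` with
#' congruent channel and mask shapes.
#'
#' @param manifest_path path to a manifest written by [write_cohort()] (or any
#'   CSV with the same columns).
#' @return list of `labeled_volume` objects.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("case_id", "label", "diagnosis_time", "channel_paths", "mask_path")
  if (!all(required %in% names(man))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(man$case_id)) stop("case_ids are not unique", call. = FALSE)
  if (!all(man$label %in% c(0L, 1L))) {
    stop("invalid label(s) in manifest: labels must be 0 or 1", call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    ch_paths <- strsplit(row$channel_paths, ";", fixed = TRUE)[[1L]]
    paths <- file.path(base, c(ch_paths, row$mask_path))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop(sprintf("case %s: file not found: %s", row$case_id,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    channels <- lapply(file.path(base, ch_paths), read_nifti_zyx)
    mask <- read_nifti_zyx(file.path(base, row$mask_path))
    shp <- dim(channels[[1L]])
    ok <- all(vapply(channels, function(c) identical(dim(c), shp), TRUE)) &&
      identical(dim(mask), shp)
    if (!ok) {
      stop(sprintf("case %s: channel/mask shapes are not congruent", row$case_id),
           call. = FALSE)
    }
    intens <- array(0, c(length(channels), shp))
    for (ch in seq_along(channels)) intens[ch, , , ] <- channels[[ch]]
    new_labeled_volume(intens, (mask != 0) * 1, row$label, row$case_id,
                       row$diagnosis_time)
  })
}

pipeline_defaults <- function() {
  list(patch_size = 33L, tumor_patch_fraction = 0.4, n_conv_layers = 6L,
       fc_neurons = 4096L, last_conv_filters = 128L, gmm_components = 64L,
       n_scales = 10L, scale_range = c(0.5, 2.0), ttest_alpha = 0.05,
       svm_c = 1.0, encoder_fit_cases = 30L, top_m = 100L,
       sgd_learning_rate = 0.005, sgd_momentum = 0.9, sgd_batch_size = 128L,
       sgd_epochs = 30L, dropout_rate = 0.5,
       conv_filters = NULL, n_patches = 50000L, n_channels = 1L,
       n_per_class = 20L, volume_shape = c(8L, 64L, 64L),
       texture_corr_length = c(4, 1.2), roi_mask = "truth",
       inference_stride = 1L, seed = 1L)
}

#' Build or load the pipeline configuration
#'
#' `pipeline_config()` returns the default configuration, optionally
#' overriding fields; `read_pipeline_config()` reads overrides from a flat
#' YAML key/value file. Unknown keys are rejected so that experiment configs
#' cannot silently contain typos.
#'
#' Defaults follow the reference protocol: 33x33 patches, 40% tumor-patch
#' sampling, 6 convolutional layers, 4096 fully connected neurons, 128 last
#' convolutional filters, 64 Gaussian mixture components, 10 scales on
#' [0.5, 2], t-test alpha 0.05, linear SVM box constraint 1, 30 encoder-fit
#' cases.
#'
#' @param ... named overrides of default fields.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  stopifnot(cfg$patch_size >= 1, cfg$n_conv_layers >= 1, cfg$fc_neurons >= 1,
            cfg$last_conv_filters >= 1, cfg$gmm_components >= 1,
            cfg$n_scales >= 1, cfg$encoder_fit_cases >= 1)
  if (cfg$scale_range[1L] >= cfg$scale_range[2L]) {
    stop("scale_range must be increasing", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with a flat mapping of config keys to values.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(pipeline_config, over)
}
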