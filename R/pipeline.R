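stage_paths <- function(workdir) {
  list(data = file.path(workdir, "data"),
       manifest = file.path(workdir, "data", "manifest.csv"),
       model = file.path(workdir, "model", "network.rds"),
       seg = file.path(workdir, "seg"),
       features = file.path(workdir, "features"),
       gmm = file.path(workdir, "encode", "gmm.json"),
       descriptors = file.path(workdir, "encode", "descriptors.csv"),
       results = file.path(workdir, "results"),
       log = file.path(workdir, "pipeline.log"))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing prerequisite artifact '%s': run stage '%s' first",
                 path, produced_by), call. = FALSE)
  }
  invisible(path)
}

log_stage <- function(paths, stage, config, seed, elapsed) {
  line <- sprintf("%s | stage=%s | config=%s | seed=%d | wall=%.2fs",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  config_hash(unclass(config)), as.integer(seed), elapsed)
  dir.create(dirname(paths$log), recursive = TRUE, showWarnings = FALSE)
  cat(line, "\n", file = paths$log, append = TRUE, sep = "")
  message(line)
}

net_from_config <- function(config) {
  network_spec(n_conv_layers = config$n_conv_layers,
               conv_filters = config$conv_filters,
               fc_neurons = config$fc_neurons,
               dropout_rate = config$dropout_rate,
               n_input_channels = config$n_channels,
               patch_size = config$patch_size)
}

#' Run one pipeline stage against a working directory
#'
#' Stages (in prerequisite order): `simulate` (phantom cohort to NIfTI +
#' manifest), `train-seg` (patch sampling + SGD training of the tumor
#' classifier), `segment` (dense inference + post-processing per case),
#' `evaluate` (segmentation DSC/PPV/sensitivity table), `extract`
#' (multi-scale ROI deep-filter responses per case), `encode` (GMM fit on
#' the encoder subset + Fisher descriptors for all cases), `classify`
#' (selection + linear SVM under LOOCV or a diagnosis-time split). Each run
#' appends a log line (stage, config hash, seed, wall time) to
#' `workdir/pipeline.log`. A missing prerequisite artifact raises an error
#' naming the stage to run first.
#'
#' @param stage one of the stage names above.
#' @param config a [pipeline_config()].
#' @param workdir working directory holding all stage artifacts.
#' @param seed integer seed for the stage's randomness.
#' @param mode for `classify`: `"loocv"` or `"timesplit"`.
#' @param cutoff for `classify` in timesplit mode: train on cases with
#'   `diagnosis_time <= cutoff` (default: half the cohort).
#' @return the stage's principal result, invisibly (also written to disk).
#' @export
run_stage <- function(stage, config = pipeline_config(), workdir = ".",
                      seed = config$seed, mode = "loocv", cutoff = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "train-seg", "segment", "evaluate", "extract",
              "encode", "classify")
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  paths <- stage_paths(workdir)
  t0 <- proc.time()[["elapsed"]]
  out <- switch(
    stage,
    "simulate" = {
      pcfg <- phantom_config(volume_shape = config$volume_shape,
                             n_channels = config$n_channels,
                             texture_corr_length = config$texture_corr_length,
                             seed = seed)
      cohort <- generate_cohort(config$n_per_class, pcfg, seed = seed)
      write_cohort(cohort, paths$data)
    },
    "train-seg" = {
      require_artifact(paths$manifest, "simulate")
      volumes <- load_cohort(paths$manifest)
      seeds <- derive_seeds(seed, 2L)
      ps <- sample_patches(volumes, config$n_patches,
                           config$tumor_patch_fraction,
                           config$patch_size, seed = seeds[1L])
      net <- build_network(net_from_config(config), seed = seeds[2L])
      net <- train_network(net, ps,
                           sgd = list(learning_rate = config$sgd_learning_rate,
                                      momentum = config$sgd_momentum,
                                      batch_size = config$sgd_batch_size,
                                      epochs = config$sgd_epochs),
                           seed = seeds[2L])
      dir.create(dirname(paths$model), recursive = TRUE, showWarnings = FALSE)
      net$geom <- NULL                       # drop the runtime geometry cache
      saveRDS(net, paths$model)
      net
    },
    "segment" = {
      require_artifact(paths$manifest, "simulate")
      require_artifact(paths$model, "train-seg")
      volumes <- load_cohort(paths$manifest)
      net <- load_network(paths$model)
      dir.create(paths$seg, recursive = TRUE, showWarnings = FALSE)
      for (v in volumes) {
        res <- segment_volume(net, v, stride = config$inference_stride)
        RNifti::writeNifti(aperm(res$probability_map, c(3L, 2L, 1L)),
                           file.path(paths$seg, sprintf("%s_prob.nii.gz", v$case_id)))
        RNifti::writeNifti(aperm(res$mask, c(3L, 2L, 1L)),
                           file.path(paths$seg, sprintf("%s_mask.nii.gz", v$case_id)))
      }
      paths$seg
    },
    "evaluate" = {
      require_artifact(paths$manifest, "simulate")
      volumes <- load_cohort(paths$manifest)
      rows <- lapply(volumes, function(v) {
        mp <- file.path(paths$seg, sprintf("%s_mask.nii.gz", v$case_id))
        require_artifact(mp, "segment")
        m <- segmentation_metrics(read_nifti_zyx(mp), v$mask)
        data.frame(case_id = v$case_id, dsc = m[["dsc"]], ppv = m[["ppv"]],
                   sensitivity = m[["sensitivity"]])
      })
      tab <- do.call(rbind, rows)
      dir.create(paths$results, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(tab, file.path(paths$results, "segmentation_metrics.csv"),
                       row.names = FALSE)
      tab
    },
    "extract" = {
      require_artifact(paths$manifest, "simulate")
      require_artifact(paths$model, "train-seg")
      volumes <- load_cohort(paths$manifest)
      net <- load_network(paths$model)
      min_input <- 2L * net$spec$n_conv_layers + 1L
      dir.create(paths$features, recursive = TRUE, showWarnings = FALSE)
      for (v in volumes) {
        mask <- if (identical(config$roi_mask, "predicted")) {
          mp <- file.path(paths$seg, sprintf("%s_mask.nii.gz", v$case_id))
          require_artifact(mp, "segment")
          read_nifti_zyx(mp)
        } else v$mask
        rois <- multiscale_rois(v, mask, config$n_scales, config$scale_range,
                                min_input = min_input)
        fr <- extract_filter_responses(net, rois)
        saveRDS(fr, file.path(paths$features, sprintf("%s_responses.rds", v$case_id)))
        jsonlite::write_json(
          list(case_id = v$case_id, n_filters = fr$n_filters,
               n_responses = fr$n_responses, scales = rois$ratios,
               ordering = "slice-major, scale, column-major raster"),
          file.path(paths$features, sprintf("%s_responses.json", v$case_id)),
          auto_unbox = TRUE, digits = NA)
      }
      paths$features
    },
    "encode" = {
      require_artifact(paths$manifest, "simulate")
      man <- utils::read.csv(paths$manifest, stringsAsFactors = FALSE)
      rfiles <- file.path(paths$features,
                          sprintf("%s_responses.rds", man$case_id))
      for (f in rfiles) require_artifact(f, "extract")
      rsets <- lapply(rfiles, readRDS)
      n_fit <- min(config$encoder_fit_cases, length(rsets))
      pool <- unlist(lapply(rsets[seq_len(n_fit)],
                            function(r) as.vector(r$responses)))
      gmm <- fit_gmm(pool, K = config$gmm_components, seed = seed)
      dir.create(dirname(paths$gmm), recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(weights = gmm$weights, means = gmm$means,
             variances = gmm$variances, K = gmm$K, loglik = gmm$loglik,
             n = gmm$n, n_iter = gmm$n_iter, seed = gmm$seed),
        paths$gmm, auto_unbox = TRUE, digits = NA)
      desc <- t(vapply(rsets, function(r) encode_case(r, gmm)$values,
                       numeric(2L * gmm$K * rsets[[1L]]$n_filters)))
      colnames(desc) <- sprintf("fv1_%05d", seq_len(ncol(desc)))
      df <- data.frame(case_id = man$case_id, desc, check.names = FALSE)
      utils::write.csv(df, paths$descriptors, row.names = FALSE)
      desc
    },
    "classify" = {
      require_artifact(paths$manifest, "simulate")
      require_artifact(paths$descriptors, "encode")
      man <- utils::read.csv(paths$manifest, stringsAsFactors = FALSE)
      df <- utils::read.csv(paths$descriptors, check.names = FALSE)
      stopifnot(identical(df$case_id, man$case_id))
      X <- as.matrix(df[, -1L, drop = FALSE])
      report <- if (identical(mode, "timesplit")) {
        if (is.null(cutoff)) cutoff <- stats::median(man$diagnosis_time)
        time_split_predict(X, man$label, man$diagnosis_time, cutoff,
                           alpha = config$ttest_alpha, m = config$top_m,
                           svm_c = config$svm_c, case_ids = man$case_id)
      } else {
        loocv_predict(X, man$label, alpha = config$ttest_alpha,
                      m = config$top_m, svm_c = config$svm_c,
                      case_ids = man$case_id)
      }
      dir.create(paths$results, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data.frame(case_id = report$case_ids,
                                  label = report$labels,
                                  score = report$scores,
                                  predicted = report$predicted),
                       file.path(paths$results, "predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(metric = c("auc", names(report$metrics)),
                                  value = c(report$auc, report$metrics)),
                       file.path(paths$results, "metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(report$roc_curve,
                       file.path(paths$results, "roc.csv"), row.names = FALSE)
      report
    })
  log_stage(paths, stage, config, seed, proc.time()[["elapsed"]] - t0)
  invisible(out)
}

#' Load a network checkpoint written by the `train-seg` stage
#'
#' @param path an `.rds` checkpoint.
#' @return a `dlr_network` with a fresh geometry cache.
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "dlr_network"))
  net$geom <- new.env(parent = emptyenv())
  net
}
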