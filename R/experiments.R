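# Desk-scale reference experiments. These are the package's own study
# conditions: a reduced segmentation network (2 conv layers of 8 and 16
# filters, 64 fully connected neurons) trained on high-contrast phantoms, and
# a 40-case phenotype cohort encoded with a compact mixture. The vignette
# discusses how they scale down the full protocol.

reduced_spec <- function(n_channels = 1L) {
  network_spec(n_conv_layers = 2L, conv_filters = c(8L, 16L),
               fc_neurons = 64L, n_input_channels = n_channels)
}

#' Held-out segmentation experiment on high-contrast phantoms
#'
#' Trains the reduced patch classifier (2 conv layers, 64 fc neurons) on
#' `n_train` phantoms (5,000 patches, 40% tumor-centred, 10 epochs of SGD)
#' and segments one held-out phantom; returns the post-processed overlap
#' metrics against the analytic ground truth.
#'
#' @param seed experiment seed (phantoms, sampling, training).
#' @param n_train number of training phantoms (default 8).
#' @param n_patches training patches (default 5000).
#' @param epochs SGD epochs (default 10).
#' @return list with `metrics` (dsc/ppv/sensitivity), `net`, `result`
#'   (the held-out `segmentation_result`), `truth`.
#' @export
run_segmentation_experiment <- function(seed = 1L, n_train = 8L,
                                        n_patches = 5000L, epochs = 10L) {
  seeds <- derive_seeds(seed, 4L)
  cfg <- phantom_config()
  case_seeds <- derive_seeds(seeds[1L], n_train + 1L)
  vols <- lapply(seq_len(n_train + 1L), function(i)
    generate_phantom(cfg, (i - 1L) %% 2L, case_seeds[i],
                     case_id = sprintf("case_%03d", i)))
  train_vols <- vols[seq_len(n_train)]
  held_out <- vols[[n_train + 1L]]
  ps <- sample_patches(train_vols, n_patches, tumor_fraction = 0.4,
                       seed = seeds[2L])
  net <- build_network(reduced_spec(), seed = seeds[3L])
  net <- train_network(net, ps, sgd = list(epochs = epochs), seed = seeds[4L])
  res <- segment_volume(net, held_out)
  list(metrics = segmentation_metrics(res$mask, held_out$mask),
       net = net, result = res, truth = held_out$mask)
}

#' End-to-end phenotype recovery experiment on a phantom cohort
#'
#' Generates a balanced cohort, trains the reduced segmentation network on a
#' modest patch sample, harvests multi-scale last-conv filter responses over
#' the ground-truth masks, fits the shared scalar mixture on the encoder
#' subset, encodes every case as an improved Fisher vector, and evaluates
#' leave-one-out phenotype prediction with the t-test filter, F-score top-m
#' ranking and a linear SVM.
#'
#' @param seed experiment seed.
#' @param n_per_class cases per phenotype class (default 20).
#' @param separated if `TRUE`, the two classes carry the default, strongly
#'   separated texture correlation lengths; if `FALSE`, both classes share
#'   one correlation length so the cohort carries no phenotype signal (a
#'   negative control).
#' @param K mixture components (default 8 at this scale).
#' @param m features kept after F-score ranking (default 50).
#' @param n_patches,epochs training budget for the reduced network.
#' @param encoder_fit_cases cases whose pooled responses fit the mixture.
#' @return list with `report` (a `prediction_report`), `descriptors`
#'   (cases x 2KF matrix), `labels`, `gmm`, `net`.
#' @export
run_phenotype_experiment <- function(seed = 1L, n_per_class = 20L,
                                     separated = TRUE, K = 8L, m = 50L,
                                     n_patches = 2000L, epochs = 3L,
                                     encoder_fit_cases = 30L) {
  seeds <- derive_seeds(seed, 5L)
  cfg <- if (separated) phantom_config() else
    phantom_config(texture_corr_length = c(2, 2))
  cohort <- generate_cohort(n_per_class, cfg, seed = seeds[1L])
  ps <- sample_patches(cohort$volumes, n_patches, tumor_fraction = 0.4,
                       seed = seeds[2L])
  net <- build_network(reduced_spec(), seed = seeds[3L])
  net <- train_network(net, ps, sgd = list(epochs = epochs), seed = seeds[4L])
  min_input <- 2L * net$spec$n_conv_layers + 1L
  rsets <- lapply(cohort$volumes, function(v) {
    # thin top/bottom tumor slices legitimately lose their smallest scales
    rois <- suppressWarnings(
      multiscale_rois(v, v$mask, n_scales = 10L, min_input = min_input))
    extract_filter_responses(net, rois)
  })
  n_fit <- min(encoder_fit_cases, length(rsets))
  pool <- unlist(lapply(rsets[seq_len(n_fit)],
                        function(r) as.vector(r$responses)))
  gmm <- fit_gmm(pool, K = K, seed = seeds[5L])
  desc <- t(vapply(rsets, function(r) encode_case(r, gmm)$values,
                   numeric(2L * K * rsets[[1L]]$n_filters)))
  labels <- cohort$manifest$label
  report <- suppressWarnings(
    loocv_predict(desc, labels, alpha = 0.05, m = m, svm_c = 1,
                  case_ids = cohort$manifest$case_id))
  list(report = report, descriptors = desc, labels = labels,
       gmm = gmm, net = net)
}
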