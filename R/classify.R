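#' Two-sample t-test filter over descriptor dimensions
#'
#' Pooled-variance (Student) two-sample t-test of every feature between the
#' two phenotype classes; features with `p < alpha` are kept. A feature with
#' zero pooled variance separates the classes perfectly when its class means
#' differ (kept, `p = 0`); when the means are equal too the test is
#' undefined and the feature is excluded with a warning.
#'
#' @param features cases x features numeric matrix.
#' @param labels 0/1 vector, one per case, both classes with >= 2 cases.
#' @param alpha significance level (default 0.05, uncorrected — deliberately
#'   no multiplicity adjustment).
#' @return list with `kept` (column indices) and `p_values` (per feature;
#'   `NA` where undefined).
#' @export
ttest_filter <- function(features, labels, alpha = 0.05) {
  features <- as.matrix(features)
  check_two_classes(labels, min_per_class = 2L)
  g1 <- labels == 1
  n1 <- sum(g1); n0 <- sum(!g1)
  m1 <- colMeans(features[g1, , drop = FALSE])
  m0 <- colMeans(features[!g1, , drop = FALSE])
  ss1 <- colSums(sweep(features[g1, , drop = FALSE], 2L, m1)^2)
  ss0 <- colSums(sweep(features[!g1, , drop = FALSE], 2L, m0)^2)
  df <- n1 + n0 - 2L
  sp2 <- (ss1 + ss0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- rep(NA_real_, ncol(features))
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs((m1[ok] - m0[ok]) / se[ok]), df)
  p[!ok & m1 != m0] <- 0                   # perfectly separated constant levels
  if (any(!ok & m1 == m0)) {
    warning(sum(!ok & m1 == m0), " feature(s) with zero pooled variance excluded")
  }
  list(kept = which(!is.na(p) & p < alpha), p_values = p)
}

check_two_classes <- function(labels, min_per_class = 1L) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop("both classes must be present with at least ", min_per_class,
         " case(s) each", call. = FALSE)
  }
  invisible(TRUE)
}

#' F-score of each feature for a binary phenotype
#'
#' The feature-selection F-score (between-class over within-class scatter of
#' a single feature):
#' \deqn{F = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
#'            {\frac{1}{n^+ - 1}\sum (x^+ - \bar x^+)^2 +
#'             \frac{1}{n^- - 1}\sum (x^- - \bar x^-)^2}}
#' Features with zero denominator score `Inf` when the numerator is positive
#' and 0 otherwise. Not the F1 classification measure.
#'
#' @inheritParams ttest_filter
#' @return numeric vector of per-feature scores (>= 0).
#' @export
fscore_rank <- function(features, labels) {
  features <- as.matrix(features)
  check_two_classes(labels, min_per_class = 2L)
  g1 <- labels == 1
  m <- colMeans(features)
  m1 <- colMeans(features[g1, , drop = FALSE])
  m0 <- colMeans(features[!g1, , drop = FALSE])
  v1 <- colSums(sweep(features[g1, , drop = FALSE], 2L, m1)^2) / (sum(g1) - 1L)
  v0 <- colSums(sweep(features[!g1, , drop = FALSE], 2L, m0)^2) / (sum(!g1) - 1L)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- v1 + v0
  out <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  as.numeric(out)
}

#' Indices of the m largest F-scores
#'
#' Ties are broken in favour of the lower index; if fewer than `m` scores are
#' available, all are returned with a warning.
#'
#' @param fscores numeric vector of scores.
#' @param m number of features to keep (>= 1).
#' @return integer indices into `fscores`.
#' @export
select_top <- function(fscores, m) {
  stopifnot(m >= 1)
  if (m > length(fscores)) {
    warning("m exceeds the number of available features; keeping all")
    m <- length(fscores)
  }
  order(-fscores, seq_along(fscores))[seq_len(m)]
}

# Linear SVM behind the classifier stage: z-scores features with
# training-fold statistics, fits e1071/libsvm with a linear kernel, and
# returns the decision score oriented so that positive favours class 1.
svm_fit_score <- function(x_train, y_train, x_test, svm_c = 1.0) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps^0.5] <- 1
  xs <- sweep(sweep(x_train, 2L, mu), 2L, sdv, "/")
  xt <- sweep(sweep(matrix(x_test, ncol = ncol(x_train)), 2L, mu), 2L, sdv, "/")
  fit <- e1071::svm(xs, factor(y_train, levels = c(0, 1)), kernel = "linear",
                    cost = svm_c, scale = FALSE)
  pr <- stats::predict(fit, xt, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- as.numeric(dv[, 1L])
  # libsvm orients the decision value toward the first label in the colname
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (first == "0") score <- -score
  score
}

# One fold's feature selection + SVM: t-test filter, F-score top-m, fit.
fold_fit_predict <- function(x_train, y_train, x_test, alpha, m, svm_c) {
  flt <- suppressWarnings(ttest_filter(x_train, y_train, alpha))
  kept <- flt$kept
  if (!length(kept)) {
    warning("no feature passed the t-test filter; ranking all well-defined features")
    kept <- which(!is.na(flt$p_values))
    if (!length(kept)) kept <- seq_len(ncol(x_train))
  }
  fs <- fscore_rank(x_train[, kept, drop = FALSE], y_train)
  top <- kept[suppressWarnings(select_top(fs, min(m, length(kept))))]
  score <- svm_fit_score(x_train[, top, drop = FALSE], y_train,
                         x_test[, top, drop = FALSE], svm_c)
  list(score = score, selected = top)
}

new_prediction_report <- function(scores, labels, case_ids = NULL) {
  predicted <- as.integer(scores > 0)
  roc <- roc_auc(scores, labels)
  cm <- confusion_metrics(predicted, labels)
  structure(list(case_ids = case_ids, scores = scores, labels = labels,
                 predicted = predicted, auc = roc$auc, roc_curve = roc$curve,
                 metrics = cm),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> n = %d | AUC %.4f | ACC %.4f | SENS %.4f | SPEC %.4f\n",
              length(x$labels), x$auc, x$metrics["acc"], x$metrics["sens"],
              x$metrics["spec"]))
  invisible(x)
}

#' Leave-one-out cross-validated phenotype prediction
#'
#' For every case, the t-test filter, F-score ranking and linear SVM
#' (box constraint `svm_c`) are re-fit on the remaining cases — selection is
#' repeated inside every fold so no information about the held-out case leaks
#' into it — and the held-out decision score is recorded. Metrics are
#' computed from the n held-out scores.
#'
#' @param features cases x features matrix.
#' @param labels 0/1 phenotype per case (n >= 4, both classes present).
#' @param alpha t-test significance level.
#' @param m number of top-F-score features given to the SVM.
#' @param svm_c linear-SVM box constraint (default 1).
#' @param case_ids optional case identifiers carried into the report.
#' @return a `prediction_report`: per-case `scores` and `predicted` labels,
#'   `auc` with `roc_curve`, and `metrics`
#'   (ACC, SENS, SPEC, PPV, NPV, MCC at decision threshold 0).
#' @export
loocv_predict <- function(features, labels, alpha = 0.05, m = 100L,
                          svm_c = 1.0, case_ids = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 cases for LOOCV", call. = FALSE)
  check_two_classes(labels)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- labels[-i]
    if (length(unique(y_tr)) < 2L) {
      stop("a fold has a single-class training set", call. = FALSE)
    }
    scores[i] <- fold_fit_predict(features[-i, , drop = FALSE], y_tr,
                                  features[i, , drop = FALSE],
                                  alpha, m, svm_c)$score
  }
  new_prediction_report(scores, labels, case_ids)
}

#' Diagnosis-time split phenotype prediction
#'
#' Single fit on the cases with `diagnosis_time <= cutoff` (the "early"
#' cohort), single evaluation on the later cases, mirroring a
#' train-before/test-after-a-date protocol.
#'
#' @inheritParams loocv_predict
#' @param diagnosis_time numeric/ordinal time per case.
#' @param cutoff cases with time `<= cutoff` train, `> cutoff` test.
#' @return a `prediction_report` for the test side.
#' @export
time_split_predict <- function(features, labels, diagnosis_time, cutoff,
                               alpha = 0.05, m = 100L, svm_c = 1.0,
                               case_ids = NULL) {
  features <- as.matrix(features)
  train <- diagnosis_time <= cutoff
  if (!any(train) || all(train)) {
    stop("cutoff leaves an empty training or test side", call. = FALSE)
  }
  y_tr <- labels[train]
  if (length(unique(y_tr)) < 2L) {
    stop("training side must contain both classes", call. = FALSE)
  }
  res <- fold_fit_predict(features[train, , drop = FALSE], y_tr,
                          features[!train, , drop = FALSE],
                          alpha, m, svm_c)
  new_prediction_report(res$score, labels[!train],
                        if (!is.null(case_ids)) case_ids[!train])
}

#' Area under the ROC curve with tie handling
#'
#' Rank-statistic (Mann-Whitney) AUC: ties between a positive and a negative
#' score earn half credit. The curve lists TPR/FPR at every distinct score
#' threshold (plus the two trivial endpoints).
#'
#' @param scores numeric decision scores (larger = more class-1-like).
#' @param labels 0/1 vector; both classes must be present.
#' @return list with `auc` and `curve` (data.frame `threshold, fpr, tpr`).
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                                  # average ranks on ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0))
  list(auc = auc, curve = curve)
}

#' Confusion-table metrics of a binary prediction
#'
#' Standard 2x2 definitions with positive class 1:
#' ACC, SENS `= TP/(TP+FN)`, SPEC `= TN/(TN+FP)`, PPV `= TP/(TP+FP)`,
#' NPV `= TN/(TN+FN)` and Matthews correlation
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any undefined ratio (empty denominator) is reported as 0 with a warning;
#' an MCC with a zero factor under the root is likewise defined as 0.
#'
#' @param predicted,labels 0/1 vectors of equal length.
#' @return named numeric vector `c(acc, sens, spec, ppv, npv, mcc)`.
#' @export
confusion_metrics <- function(predicted, labels) {
  if (length(predicted) != length(labels)) {
    stop("length mismatch between predicted and labels", call. = FALSE)
  }
  stopifnot(all(predicted %in% c(0, 1)), all(labels %in% c(0, 1)))
  tp <- sum(predicted == 1 & labels == 1)
  tn <- sum(predicted == 0 & labels == 0)
  fp <- sum(predicted == 1 & labels == 0)
  fn <- sum(predicted == 0 & labels == 1)
  div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (empty denominator); returning 0"); 0 }
    else num / den
  }
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warning("mcc undefined (zero denominator factor); returning 0"); 0
  } else (tp * tn - fp * fn) / mcc_den
  c(acc = (tp + tn) / length(labels),
    sens = div(tp, tp + fn, "sens"),
    spec = div(tn, tn + fp, "spec"),
    ppv = div(tp, tp + fp, "ppv"),
    npv = div(tn, tn + fn, "npv"),
    mcc = mcc)
}
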