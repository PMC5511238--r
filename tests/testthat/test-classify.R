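test_that("the t-test filter keeps separating features and drops flat ones", {
  set.seed(1)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(y + rnorm(20, sd = 0.01),       # near-perfect separation
             rnorm(20),                       # noise
             rep(2, 20))                      # zero pooled variance
  expect_warning(res <- ttest_filter(X, y, alpha = 0.05), "zero pooled variance")
  expect_true(1 %in% res$kept)
  expect_false(3 %in% res$kept)
  expect_true(is.na(res$p_values[3]))
  expect_lt(res$p_values[1], 1e-10)
  # identical in both classes -> not kept
  X2 <- cbind(rep(c(1, 2), 10), y + rnorm(20, sd = 0.05))
  res2 <- ttest_filter(X2, y, alpha = 0.05)
  expect_false(1 %in% res2$kept)
  # alpha = 1 keeps all well-defined features
  expect_warning(res3 <- ttest_filter(X, y, alpha = 1), "zero pooled")
  expect_setequal(res3$kept, c(1, 2))
  # nesting across alphas
  set.seed(2)
  Xr <- matrix(rnorm(20 * 30), 20, 30)
  k1 <- ttest_filter(Xr, y, 0.01)$kept
  k2 <- ttest_filter(Xr, y, 0.2)$kept
  expect_true(all(k1 %in% k2))
  expect_error(ttest_filter(X, rep(1, 20)), "both classes")
})

test_that("F-scores match hand arithmetic and are scale invariant", {
  x <- c(1, 2, 3, 7, 8, 9)
  y <- c(1, 1, 1, 0, 0, 0)
  # grand mean 5, class means 2 and 8 -> numerator 18, denominator 2 -> F = 9
  expect_equal(fscore_rank(cbind(x), y), 9)
  expect_equal(fscore_rank(cbind(x * 13.7), y), 9, tolerance = 1e-12)
  # equal class means -> score 0
  x0 <- c(1, 3, 2, 1, 3, 2)
  expect_equal(fscore_rank(cbind(x0), y), 0)
  # zero within-class variance with separation -> Inf
  xc <- c(1, 1, 1, 2, 2, 2)
  expect_equal(fscore_rank(cbind(xc), y), Inf)
  expect_true(all(fscore_rank(matrix(rnorm(60), 6), y) >= 0))
})

test_that("top-m selection breaks ties toward the lower index", {
  expect_identical(sort(select_top(c(3, 1, 2), 2)), c(1L, 3L))
  expect_identical(select_top(c(2, 2, 1), 1), 1L)
  expect_identical(sort(select_top(c(1, 2, 3), 3)), 1:3)
  expect_warning(all_idx <- select_top(c(1, 2), 5), "keeping all")
  expect_identical(sort(all_idx), 1:2)
})

test_that("LOOCV is perfect on a label-revealing feature and errors on tiny n", {
  set.seed(4)
  y <- rep(c(0, 1), 10)
  X <- cbind(y, matrix(rnorm(20 * 20), 20, 20))
  rep1 <- loocv_predict(X, y, m = 5)
  expect_equal(rep1$auc, 1)
  expect_equal(unname(rep1$metrics["acc"]), 1)
  expect_equal(unname(rep1$metrics["mcc"]), 1)
  expect_error(loocv_predict(X[1:3, ], y[1:3]), "at least 4")
})

test_that("LOOCV on pure noise stays near chance", {
  set.seed(12)
  y <- rep(c(0, 1), each = 20)
  X <- matrix(rnorm(40 * 60), 40, 60)
  rep1 <- suppressWarnings(loocv_predict(X, y, m = 10))
  expect_gte(rep1$auc, 0.3)
  expect_lte(rep1$auc, 0.7)
})

test_that("every LOOCV fold is reproducible in isolation", {
  set.seed(6)
  y <- rep(c(0, 1), 8)
  X <- cbind(y + rnorm(16, sd = 0.5), matrix(rnorm(16 * 10), 16, 10))
  rep1 <- loocv_predict(X, y, m = 4)
  for (i in c(1L, 7L, 16L)) {
    fold <- dlradiomics:::fold_fit_predict(X[-i, , drop = FALSE], y[-i],
                                           X[i, , drop = FALSE],
                                           alpha = 0.05, m = 4, svm_c = 1)
    expect_identical(fold$score, rep1$scores[i])
  }
})

test_that("the diagnosis-time split trains early and scores late cases", {
  set.seed(8)
  y <- rep(c(0, 1), 10)
  X <- cbind(y, matrix(rnorm(20 * 5), 20, 5))
  tt <- seq_len(20)
  rep1 <- time_split_predict(X, y, tt, cutoff = 10, m = 3)
  expect_length(rep1$scores, 10L)
  expect_equal(rep1$auc, 1)
  expect_error(time_split_predict(X, y, tt, cutoff = 30), "empty")
  expect_error(time_split_predict(X, y, tt, cutoff = 0), "empty")
  y_bad <- c(rep(0, 10), rep(1, 10))
  expect_error(time_split_predict(X, y_bad, tt, cutoff = 10), "both classes")
})

test_that("rank AUC equals brute-force pairwise concordance on random vectors", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- if (runif(1) < 0.3) sample(1:4, n, replace = TRUE) else rnorm(n)
    expect_identical(roc_auc(s, y)$auc, auc_bruteforce(s, y))
  }
})

test_that("AUC handles ties and score negation coherently", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(14)
  s <- rnorm(12); y <- rep(c(0, 1), 6)
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
  curve <- roc_auc(s, y)$curve
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_error(roc_auc(s, rep(1, 12)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(15)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("confusion metrics match hand-computed tables", {
  pred <- c(rep(1, 4), rep(0, 6))
  lab <- c(rep(1, 3), 0, rep(0, 4), 1, 1)   # TP=3 FP=1 TN=4 FN=2
  m <- confusion_metrics(pred, lab)
  expect_equal(unname(m), c(0.7, 0.6, 0.8, 0.75, 2 / 3, 10 / sqrt(600)))
  # perfect and inverted predictions
  y <- rep(c(0, 1), 5)
  expect_equal(unname(confusion_metrics(y, y)), rep(1, 6))
  expect_equal(unname(confusion_metrics(1 - y, y)["mcc"]), -1)
  # degenerate denominators yield 0 with warnings
  w <- capture_warnings(m0 <- confusion_metrics(rep(0, 4), c(0, 0, 1, 1)))
  expect_true(all(grepl("undefined", w)))   # ppv and mcc both warn
  expect_equal(unname(m0["ppv"]), 0)
  expect_equal(unname(m0["mcc"]), 0)
  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), "length mismatch")
})

test_that("confusion metrics match exhaustive enumeration of small tables", {
  for (tp in 0:4) for (fp in 0:4) for (tn in 0:4) for (fn in 0:4) {
    n <- tp + fp + tn + fn
    if (n == 0) next
    pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
    lab <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
    m <- suppressWarnings(confusion_metrics(pred, lab))
    expect_equal(unname(m["acc"]), (tp + tn) / n)
    expect_equal(unname(m["sens"]), if (tp + fn > 0) tp / (tp + fn) else 0)
    expect_equal(unname(m["spec"]), if (tn + fp > 0) tn / (tn + fp) else 0)
    expect_equal(unname(m["ppv"]), if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(unname(m["npv"]), if (tn + fn > 0) tn / (tn + fn) else 0)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(unname(m["mcc"]),
                 if (den > 0) (tp * tn - fp * fn) / den else 0)
  }
})
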