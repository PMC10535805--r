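# Metrics and split protocols.

test_that("confusion rates follow the four formulas", {
  m <- confusion_metrics(list(TP = 3, FN = 1, FP = 2, TN = 4))
  expect_equal(m$TPR, 0.75)
  expect_equal(m$FPR, 1 / 3)
  expect_equal(m$Precision, 0.6)
  expect_equal(m$Recall, 0.75)
  expect_equal(confusion_metrics(list(TP = 5, FN = 5, FP = 0, TN = 1))$TPR, 0.5)
  expect_equal(confusion_metrics(list(TP = 2, FN = 0, FP = 0, TN = 1))$Precision, 1)
  expect_warning(out <- confusion_metrics(list(TP = 0, FN = 1, FP = 0, TN = 1)),
                 "Precision undefined")
  expect_true(is.nan(out$Precision))
})

test_that("ROC AUC equals exhaustive concordant-pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9), c(1, 1, 0)), 0)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)     # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC/PR areas agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-10)
})

test_that("random scores give AUC near one half", {
  set.seed(123)
  scores <- runif(2000)
  labels <- rbinom(2000, 1, 0.3)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
})

test_that("PR AUC integrates step-wise and is 1 for perfect ranking", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-computed small case: order 0.9(1), 0.8(0), 0.7(1), 0.6(0)
  # steps: R=0.5 at P=1; R=1 at P=2/3
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  crd <- curve_coordinates(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(crd$roc$TPR, c(0, 0.5, 0.5, 1, 1))
  expect_equal(utils::tail(crd$pr$Recall, 1), 1)
})

test_that("split plans respect the cold-start disjointness contracts", {
  set.seed(4)
  pairs <- expand.grid(drug = paste0("d", 1:12), protein = paste0("t", 1:15),
                       stringsAsFactors = FALSE)
  pairs$y <- rbinom(nrow(pairs), 1, 0.2)
  for (mode in c("random", "blind_drug", "blind_protein", "blind_pair")) {
    plan <- make_splits(pairs, mode, k = 4, seed = 7)
    expect_silent(audit_splits(plan))
    for (f in plan$folds) {
      tr <- pairs[f$train, ]; te <- pairs[f$test, ]
      if (mode %in% c("blind_drug", "blind_pair")) {
        expect_length(intersect(tr$drug, te$drug), 0)
      }
      if (mode %in% c("blind_protein", "blind_pair")) {
        expect_length(intersect(tr$protein, te$protein), 0)
      }
    }
  }
  # random folds cover every pair exactly once as test
  plan <- make_splits(pairs, "random", k = 5, seed = 1)
  tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(tested, seq_len(nrow(pairs)))
  # stratification keeps fold-wise positive rates close
  rates <- vapply(plan$folds, function(f) mean(pairs$y[f$test]), 1)
  expect_lt(diff(range(rates)), 0.05)
  expect_error(make_splits(pairs, "blind_drug", k = 40, seed = 1), "exceeds")
})

test_that("cross-validation report has fold rows, a mean row and fixed seed", {
  b <- small_bundle(seed = 8L)
  cv <- run_cv(b, fast_config(seed = 5), mode = "random", k = 4, max_folds = 2)
  expect_equal(sum(!is.na(cv$report$fold)), 2)
  mrow <- cv$report[is.na(cv$report$fold), ]
  expect_equal(mrow$auc, mean(cv$report$auc[!is.na(cv$report$fold)]))
  expect_equal(mrow$aupr, mean(cv$report$aupr[!is.na(cv$report$fold)]))
  cv2 <- run_cv(b, fast_config(seed = 5), mode = "random", k = 4, max_folds = 2)
  expect_identical(cv$report, cv2$report)
})
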