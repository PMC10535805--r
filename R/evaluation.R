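# Evaluation: confusion-matrix rates, ROC / precision-recall areas,
# stratified and cold-start (blind drug / blind protein / blind pair)
# split plans, and the cross-validated end-to-end runner.

#' Confusion-count rates
#'
#' TPR = TP / (TP + FN), FPR = FP / (TN + FP),
#' Precision = TP / (TP + FP), Recall = TP / (TP + FN).
#' A zero denominator yields NaN with a warning.
#'
#' @param counts List or vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named list `TPR`, `FPR`, `Precision`, `Recall`.
#' @export
confusion_metrics <- function(counts) {
  counts <- as.list(counts)
  rate <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", name))
      return(NaN)
    }
    num / den
  }
  with(counts, list(
    TPR = rate(TP, TP + FN, "TPR"),
    FPR = rate(FP, TN + FP, "FPR"),
    Precision = rate(TP, TP + FP, "Precision"),
    Recall = rate(TP, TP + FN, "Recall")))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over all thresholds, equal to the
#' Mann-Whitney concordance statistic; ties receive midranks.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return Numeric in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: descending unique score thresholds, with
#' `AUPR = sum (R_t - R_{t-1}) P_t`.
#'
#' @inheritParams roc_auc
#' @return Numeric in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0L || n1 == length(labels)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied thresholds: keep the last index of each score group
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall curve coordinates
#'
#' @inheritParams roc_auc
#' @return List of two data frames, `roc` (FPR, TPR) and `pr`
#'   (Recall, Precision), suitable for TSV export or plotting.
#' @export
curve_coordinates <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  n1 <- sum(y); n0 <- length(y) - n1
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  list(roc = data.frame(FPR = c(0, fp / n0), TPR = c(0, tp / n1)),
       pr = data.frame(Recall = tp / n1, Precision = tp / (tp + fp)))
}

#' Cross-validation split plans, random and cold-start
#'
#' `random`: stratified k-fold over pairs (fold-wise positive rate kept
#' constant). `blind_drug`: drugs are partitioned into k groups and a
#' fold's test pairs are those whose drug is held out, so train and test
#' drug sets never overlap. `blind_protein` is symmetric.
#' `blind_pair`: drugs and proteins are both partitioned; test pairs
#' have both ends held out and pairs with mixed membership are discarded
#' from both sides.
#'
#' @param pairs Data frame with columns `drug`, `protein`, `y`.
#' @param mode One of `"random"`, `"blind_drug"`, `"blind_protein"`,
#'   `"blind_pair"`.
#' @param k Fold count.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: list with `mode`, `k`, `seed`
#'   and `folds`, each fold holding `train` / `test` row indices.
#' @export
make_splits <- function(pairs, mode = c("random", "blind_drug",
                                        "blind_protein", "blind_pair"),
                        k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(pairs)
  assign_groups <- function(ids) {
    ids <- sample(ids)
    if (k > length(ids)) stop("k exceeds the number of distinct entities")
    setNames(rep_len(seq_len(k), length(ids)), ids)
  }
  folds <- vector("list", k)
  if (mode == "random") {
    fold_of <- integer(n)
    for (cls in unique(pairs$y)) {
      idx <- sample(which(pairs$y == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      folds[[f]] <- list(train = which(fold_of != f), test = which(fold_of == f))
    }
  } else if (mode %in% c("blind_drug", "blind_protein")) {
    col <- if (mode == "blind_drug") "drug" else "protein"
    g <- assign_groups(unique(pairs[[col]]))
    fold_of <- g[pairs[[col]]]
    for (f in seq_len(k)) {
      folds[[f]] <- list(train = which(fold_of != f), test = which(fold_of == f))
    }
  } else {
    gd <- assign_groups(unique(pairs$drug))
    gp <- assign_groups(unique(pairs$protein))
    fd <- gd[pairs$drug]; fp <- gp[pairs$protein]
    for (f in seq_len(k)) {
      folds[[f]] <- list(train = which(fd != f & fp != f),
                         test = which(fd == f & fp == f))
    }
  }
  structure(list(mode = mode, k = k, seed = seed, folds = folds,
                 pairs = pairs), class = "split_plan")
}

#' Audit a split plan for id leakage
#'
#' Verifies fold-wise disjointness of the entity sets implied by the
#' mode (drugs, proteins, or both) and, in random mode, that every pair
#' is tested exactly once.
#'
#' @param plan A `split_plan`.
#' @return TRUE invisibly; errors on leakage.
#' @export
audit_splits <- function(plan) {
  p <- plan$pairs
  for (f in plan$folds) {
    if (plan$mode %in% c("blind_drug", "blind_pair")) {
      if (length(intersect(p$drug[f$train], p$drug[f$test])) > 0L) {
        stop("drug id leakage between train and test")
      }
    }
    if (plan$mode %in% c("blind_protein", "blind_pair")) {
      if (length(intersect(p$protein[f$train], p$protein[f$test])) > 0L) {
        stop("protein id leakage between train and test")
      }
    }
  }
  if (plan$mode == "random") {
    tested <- sort(unlist(lapply(plan$folds, `[[`, "test")))
    if (!identical(tested, seq_len(nrow(p)))) {
      stop("random folds must cover every pair exactly once")
    }
  }
  invisible(TRUE)
}
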