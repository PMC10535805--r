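# Pair descriptors, class-imbalance resampling, and the random-forest
# interaction classifier (with a multilayer-perceptron alternative used
# by the classifier ablation).

#' Build fusion descriptors for drug-target pairs
#'
#' The descriptor of pair (i, j) is the ordered concatenation
#' `[X_D(i), X_T(j)]` (drug first), length `2 d`.
#'
#' @param X_D Drug embedding matrix with drug ids as rownames.
#' @param X_T Target embedding matrix with protein ids as rownames.
#' @param pairs Data frame with columns `drug`, `protein`.
#' @return Numeric matrix, one row per pair, `2 d` columns.
#' @export
fuse_descriptor <- function(X_D, X_T, pairs) {
  ia <- match(pairs$drug, rownames(X_D))
  ib <- match(pairs$protein, rownames(X_T))
  if (anyNA(ia)) stop(sprintf("unknown drug id: %s",
                              pairs$drug[which(is.na(ia))[1L]]))
  if (anyNA(ib)) stop(sprintf("unknown protein id: %s",
                              pairs$protein[which(is.na(ib))[1L]]))
  cbind(X_D[ia, , drop = FALSE], X_T[ib, , drop = FALSE])
}

#' Balance positive and negative pairs
#'
#' Over-samples positives (duplication with replacement) and
#' under-samples negatives (without replacement) until the class counts
#' reach `ratio` (positives : negatives, default 1:1). The per-class
#' target size is the geometric mean of the input class sizes, so both
#' operations genuinely occur and an already balanced set is returned
#' unchanged. Fully seeded.
#'
#' @param pairs Data frame with columns `drug`, `protein`, `y` (0/1).
#' @param ratio Positive:negative ratio after balancing.
#' @param seed Integer seed.
#' @return Resampled data frame (row indices may repeat for positives).
#' @export
balance_samples <- function(pairs, ratio = 1, seed = 1L) {
  pos <- which(pairs$y == 1)
  neg <- which(pairs$y == 0)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("balancing requires at least one pair of each class")
  }
  m <- max(1L, round(sqrt(length(pos) * length(neg))))
  n_pos <- max(1L, round(m * ratio))
  n_neg <- m
  set.seed(seed)
  take_pos <- if (n_pos == length(pos)) pos
              else sample(pos, n_pos, replace = n_pos > length(pos))
  take_neg <- if (n_neg == length(neg)) neg
              else sample(neg, n_neg, replace = FALSE)
  out <- pairs[c(take_pos, take_neg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train the random-forest interaction classifier
#'
#' Bagged decision-tree ensemble over the fusion descriptors with
#' probability voting; defaults: 500 trees, sqrt(p) candidate features
#' per split.
#'
#' @param descriptors Numeric matrix (pairs x features).
#' @param labels 0/1 vector.
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @return Object of class `dti_classifier`.
#' @export
train_rf <- function(descriptors, labels, ntree = 500L, seed = 1L) {
  if (length(unique(labels)) < 2L) stop("training labels contain one class")
  set.seed(seed)
  fit <- randomForest::randomForest(descriptors, factor(labels, levels = c(0, 1)),
                                    ntree = ntree)
  structure(list(kind = "rf", fit = fit, p = ncol(descriptors)),
            class = "dti_classifier")
}

#' Train the multilayer-perceptron head (classifier ablation)
#'
#' Single-hidden-layer perceptron on the fusion descriptors, the
#' end-to-end style alternative to the random forest.
#'
#' @inheritParams train_rf
#' @param size Hidden units.
#' @param decay Weight decay.
#' @return Object of class `dti_classifier`.
#' @export
train_mlp <- function(descriptors, labels, size = 16L, decay = 1e-4,
                      seed = 1L) {
  if (length(unique(labels)) < 2L) stop("training labels contain one class")
  set.seed(seed)
  fit <- nnet::nnet(descriptors, matrix(labels, ncol = 1L), size = size,
                    decay = decay, maxit = 300L, entropy = TRUE,
                    trace = FALSE, MaxNWts = 1e6)
  structure(list(kind = "mlp", fit = fit, p = ncol(descriptors)),
            class = "dti_classifier")
}

#' Score drug-target pair descriptors
#'
#' @param object A `dti_classifier`.
#' @param descriptors Numeric matrix with the training feature width.
#' @param threshold Probability cut-off for the hard label (default 0.5).
#' @param ... Unused.
#' @return Data frame `score` (interaction probability) and `label`
#'   (0/1 at the threshold).
#' @export
predict.dti_classifier <- function(object, descriptors, threshold = 0.5, ...) {
  if (nrow(descriptors) == 0L) {
    return(data.frame(score = numeric(0), label = integer(0)))
  }
  if (ncol(descriptors) != object$p) stop("descriptor length mismatch")
  score <- if (object$kind == "rf") {
    unname(stats::predict(object$fit, descriptors, type = "prob")[, "1"])
  } else {
    as.vector(stats::predict(object$fit, descriptors))
  }
  data.frame(score = score, label = as.integer(score > threshold))
}
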