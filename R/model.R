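# The user-facing fitting interface. dti_fit() composes the full
# pipeline -- sequence encoding, similarity-augmented network assembly,
# joint sequence/graph representation learning, descriptor fusion and
# the random-forest classifier -- and returns a classed model object
# with predict/print/summary/plot methods. Ablation switches mirror the
# four study variants: "bio" (random initial node features), "het"
# (no graph layers), "sim" (no similarity edges), "rf" (perceptron head).

#' Run configuration
#'
#' All tunable parameters of the pipeline with their defaults: k-mer
#' width 3 with the full 20^k protein vocabulary plus an unknown
#' channel; the frozen 61-token SMILES vocabulary; padded lengths at the
#' 95th-percentile corpus length rounded up to a multiple of 8; 64
#' convolution kernels and 2 aggregation blocks; graph layers
#' GCN-GAT-GCN of width 128 with 4 attention heads; Adam at 1e-3 for up
#' to 200 epochs with early-stopping patience 20 on a 10% validation
#' split; similarity threshold 0.5 for both entity kinds; 1:1 balanced
#' resampling; 500-tree random forest; decision threshold 0.5.
#'
#' @param ... Named overrides of any default.
#' @return List of class `dti_config`.
#' @export
dti_config <- function(...) {
  cfg <- list(
    k = 3L, vocab_mode = "full", unk = TRUE, policy = "unk",
    L_D = NULL, L_T = NULL,
    n_kernels = 64L, n_blocks = 2L,
    d_hidden = 128L, d = 128L, K = 4L, db = 8L,
    layer_order = c("gcn", "gat", "gcn"),
    lr = 1e-3, epochs = 200L, patience = 20L, val_frac = 0.1,
    sim_threshold_drug = 0.5, sim_threshold_protein = 0.5,
    balance_ratio = 1, rf_ntree = 500L, mlp_size = 16L,
    threshold = 0.5, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "dti_config")
}

# drug and target similarity sources (3 network + fingerprint for drugs;
# 2 network + sequence for targets)
.drug_similarities <- function(bundle) {
  list(jaccard_network_similarity(bundle$drug_disease, "network-disease"),
       jaccard_network_similarity(bundle$ddi, "network-interaction"),
       jaccard_network_similarity(bundle$drug_side_effect, "network-sideeffect"),
       fingerprint_similarity(bundle$drugs))
}

.target_similarities <- function(bundle) {
  list(jaccard_network_similarity(bundle$target_disease, "network-disease"),
       jaccard_network_similarity(bundle$tti, "network-interaction"),
       sequence_similarity_matrix(bundle$proteins))
}

# all drug x target cells as a labelled pair frame
all_pairs <- function(bundle) {
  data.frame(drug = rep(rownames(bundle$dti), ncol(bundle$dti)),
             protein = rep(colnames(bundle$dti), each = nrow(bundle$dti)),
             y = as.vector(bundle$dti), stringsAsFactors = FALSE)
}

#' Fit the drug-target interaction model
#'
#' @param bundle A `dti_bundle` (see [generate_dataset()] /
#'   [load_bundle()]).
#' @param config A [dti_config()].
#' @param ablate Character subset of `c("bio", "het", "sim", "rf")`:
#'   replace initial node features by random vectors, skip the graph
#'   layers, drop similarity edges, or swap the random forest for a
#'   perceptron head.
#' @param train_pairs Optional data frame `drug`, `protein`, `y`
#'   restricting training to these pairs (cross-validation uses this;
#'   the default trains on every drug x target cell). Only pairs given
#'   here contribute interaction edges to the network.
#' @return Object of class `dti_model`.
#' @export
dti_fit <- function(bundle, config = dti_config(), ablate = character(0),
                    train_pairs = NULL) {
  stopifnot(inherits(bundle, "dti_bundle"), inherits(config, "dti_config"))
  stopifnot(all(ablate %in% c("bio", "het", "sim", "rf")))
  if (is.null(train_pairs)) train_pairs <- all_pairs(bundle)

  drug_ids <- sort(names(bundle$drugs))
  protein_ids <- sort(names(bundle$proteins))

  # similarity edges (dropped under the "sim" ablation)
  if ("sim" %in% ablate) {
    d_edges <- p_edges <- NULL
  } else {
    d_edges <- add_similarity_edges(.drug_similarities(bundle),
                                    config$sim_threshold_drug,
                                    existing = bundle$ddi)
    p_edges <- add_similarity_edges(.target_similarities(bundle),
                                    config$sim_threshold_protein,
                                    existing = bundle$tti)
  }

  # interaction edges come from the training positives only
  dpi <- bundle$dti * 0L
  pos <- train_pairs[train_pairs$y == 1, , drop = FALSE]
  dpi[cbind(match(pos$drug, rownames(dpi)), match(pos$protein, colnames(dpi)))] <- 1L
  net <- assemble_network(drug_ids, protein_ids,
                          ddi = bundle$ddi, dpi = dpi, ppi = bundle$tti,
                          drug_sim_edges = d_edges, protein_sim_edges = p_edges)

  # sequence encoding (skipped under the "bio" ablation)
  use_cnn <- !("bio" %in% ablate)
  embs_d <- embs_p <- cnn_d <- cnn_p <- NULL
  p_vocab <- s_vocab <- NULL
  if (use_cnn) {
    p_vocab <- build_kmer_vocabulary(bundle$proteins, k = config$k,
                                     mode = config$vocab_mode,
                                     unk = config$unk)
    s_vocab <- default_smiles_vocabulary()
    d_tok <- lapply(bundle$drugs[drug_ids], tokenize_smiles)
    p_len <- nchar(bundle$proteins[protein_ids]) - config$k + 1L
    L_D <- if (is.null(config$L_D)) default_padded_length(lengths(d_tok))
           else config$L_D
    L_T <- if (is.null(config$L_T)) default_padded_length(p_len)
           else config$L_T
    embs_d <- lapply(drug_ids, function(i)
      encode_drug(bundle$drugs[[i]], s_vocab, L_D, config$policy, id = i))
    embs_p <- lapply(protein_ids, function(i)
      encode_protein(bundle$proteins[[i]], p_vocab, L_T, config$policy, id = i))
    cnn_d <- init_cnn_params(s_vocab$size, config$n_kernels, config$n_blocks,
                             seed = config$seed + 1L)
    cnn_p <- init_cnn_params(p_vocab$size, config$n_kernels, config$n_blocks,
                             seed = config$seed + 2L)
  }

  # graph encoder (skipped under the "het" ablation)
  use_graph <- !("het" %in% ablate)
  struct <- if (use_graph) {
    init_encoder_params(config$n_kernels, config$d_hidden, config$d,
                        K = config$K, db = config$db,
                        layer_order = config$layer_order,
                        seed = config$seed + 3L)
  }

  # train/validation pair split (stratified), then balance the training side
  set.seed(config$seed + 4L)
  val_idx <- unlist(lapply(split(seq_len(nrow(train_pairs)), train_pairs$y),
                           function(ix) sample(ix, max(1L, round(
                             length(ix) * config$val_frac)))))
  val_pairs <- train_pairs[val_idx, , drop = FALSE]
  fit_pairs <- train_pairs[-val_idx, , drop = FALSE]
  bal <- balance_samples(fit_pairs, ratio = config$balance_ratio,
                         seed = config$seed + 5L)
  key <- paste(bal$drug, bal$protein)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  first <- bal[!duplicated(key), , drop = FALSE]
  first <- first[match(agg$key, paste(first$drug, first$protein)), ]
  first$w <- agg$Freq
  data <- prepare_training_data(net, embs_d, embs_p, first, val_pairs, config)

  trained <- train_encoder(data, struct, cnn_d, cnn_p, config)
  emb <- final_embeddings(trained, data, struct)
  X_D <- emb$X_D; rownames(X_D) <- drug_ids
  X_T <- emb$X_T; rownames(X_T) <- protein_ids

  # classifier on the balanced (resampled multiset) descriptors
  Z <- fuse_descriptor(X_D, X_T, bal)
  clf <- if ("rf" %in% ablate) {
    train_mlp(Z, bal$y, size = config$mlp_size, seed = config$seed + 6L)
  } else {
    train_rf(Z, bal$y, ntree = config$rf_ntree, seed = config$seed + 6L)
  }

  structure(list(config = config, ablate = ablate,
                 net = net, X_D = X_D, X_T = X_T,
                 classifier = clf, trained = trained, struct = struct,
                 log = trained$log, n_sim_edges = c(
                   drug = if (is.null(d_edges)) 0L else nrow(d_edges),
                   protein = if (is.null(p_edges)) 0L else nrow(p_edges))),
            class = "dti_model")
}

#' Predict interaction probabilities for drug-target pairs
#'
#' @param object A `dti_model`.
#' @param pairs Data frame with columns `drug`, `protein`.
#' @param ... Unused.
#' @return `pairs` with `score` and `label` columns appended.
#' @export
predict.dti_model <- function(object, pairs, ...) {
  Z <- fuse_descriptor(object$X_D, object$X_T, pairs)
  out <- predict(object$classifier, Z, threshold = object$config$threshold)
  cbind(pairs[, c("drug", "protein"), drop = FALSE], out)
}

#' @export
print.dti_model <- function(x, ...) {
  cat("Drug-target interaction model\n")
  cat(sprintf("  nodes: %d drugs, %d proteins\n",
              length(x$net$drug_ids), length(x$net$protein_ids)))
  cat(sprintf("  similarity edges: %d drug, %d protein\n",
              x$n_sim_edges[["drug"]], x$n_sim_edges[["protein"]]))
  cat(sprintf("  embedding dimension: %d\n", ncol(x$X_D)))
  cat(sprintf("  classifier: %s\n", x$classifier$kind))
  if (length(x$ablate) > 0L) {
    cat(sprintf("  ablated: %s\n", paste(x$ablate, collapse = ", ")))
  }
  cat(sprintf("  training: %d epochs (best %d), final val loss %.4f\n",
              nrow(x$log), x$trained$best_epoch, min(x$log$val)))
  invisible(x)
}

#' @export
summary.dti_model <- function(object, ...) {
  rel_sizes <- vapply(object$net$relations, function(S) sum(S) / 2, 1)
  out <- list(relations = rel_sizes, log = object$log,
              ablate = object$ablate, d = ncol(object$X_D))
  class(out) <- "summary.dti_model"
  out
}

#' @export
print.summary.dti_model <- function(x, ...) {
  cat("Relation edge counts:\n")
  print(x$relations)
  cat(sprintf("Embedding dimension: %d\n", x$d))
  cat(sprintf("Epochs run: %d; best validation loss %.4f\n",
              nrow(x$log), min(x$log$val)))
  invisible(x)
}

#' Plot the training and validation loss curves
#' @param x A `dti_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dti_model <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train, x$log$val), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Builds a split plan over every drug x target cell, refits the model
#' on each fold's training pairs only (interaction edges in the network
#' are restricted to training positives; resampling touches the
#' training side only) and scores the untouched test pairs.
#'
#' @param bundle A `dti_bundle`.
#' @param config A [dti_config()].
#' @param mode Split mode (see [make_splits()]).
#' @param k Fold count (default 5).
#' @param ablate Passed to [dti_fit()].
#' @param max_folds Evaluate only the first `max_folds` folds (desk-scale
#'   runs; default all).
#' @param seed Integer seed (defaults to the configuration seed).
#' @return Object of class `dti_cv`: data frame of per-fold AUC/AUPR
#'   plus a mean row, with the split plan attached.
#' @export
run_cv <- function(bundle, config = dti_config(), mode = "random", k = 5L,
                   ablate = character(0), max_folds = k,
                   seed = config$seed) {
  pairs <- all_pairs(bundle)
  plan <- make_splits(pairs, mode = mode, k = k, seed = seed)
  audit_splits(plan)
  rows <- list()
  scores <- list()
  for (f in seq_len(min(k, max_folds))) {
    fold <- plan$folds[[f]]
    cfg <- config
    cfg$seed <- config$seed + 1000L * f
    fit <- dti_fit(bundle, cfg, ablate = ablate,
                   train_pairs = pairs[fold$train, , drop = FALSE])
    test <- pairs[fold$test, , drop = FALSE]
    pr <- predict(fit, test)
    rows[[f]] <- data.frame(fold = f,
                            auc = roc_auc(pr$score, test$y),
                            aupr = pr_auc(pr$score, test$y))
    scores[[f]] <- cbind(test, score = pr$score)
  }
  report <- do.call(rbind, rows)
  report <- rbind(report,
                  data.frame(fold = NA, auc = mean(report$auc),
                             aupr = mean(report$aupr)))
  structure(list(report = report, plan = plan, mode = mode,
                 scores = do.call(rbind, scores)),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d folds evaluated)\n", x$mode,
              sum(!is.na(x$report$fold))))
  print(x$report, row.names = FALSE)
  invisible(x)
}
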