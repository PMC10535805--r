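# Shared fixtures: tiny deterministic networks and a lazy cache for the
# expensive end-to-end runs so several tests can share one fitted model.

# small heterogeneous network with every relation populated
tiny_hetnet <- function(seed = 1L, n_d = 4L, n_p = 5L, p = 0.4) {
  set.seed(seed)
  did <- sprintf("d%02d", seq_len(n_d))
  tid <- sprintf("t%02d", seq_len(n_p))
  symm <- function(n) {
    M <- matrix(rbinom(n * n, 1L, p), n, n)
    M <- pmax(M, t(M)); diag(M) <- 0L
    M
  }
  ddi <- symm(n_d); dimnames(ddi) <- list(did, did)
  tti <- symm(n_p); dimnames(tti) <- list(tid, tid)
  dpi <- matrix(rbinom(n_d * n_p, 1L, p), n_d, n_p, dimnames = list(did, tid))
  ds <- data.frame(id_a = did[1], id_b = did[3], score = 0.9, source = "x",
                   stringsAsFactors = FALSE)
  if (ddi[1, 3] == 1L) ds <- ds[0, ]
  ps <- data.frame(id_a = tid[2], id_b = tid[4], score = 0.8, source = "x",
                   stringsAsFactors = FALSE)
  if (tti[2, 4] == 1L) ps <- ps[0, ]
  assemble_network(did, tid, ddi, dpi, tti, ds, ps)
}

# per-node loop oracle for the relational graph convolution
gcn_loop_oracle <- function(X, net, W) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(W[[1]]))
  for (r in hetdti:::HETNET_RELATIONS) {
    S <- net$relations[[r]] + diag(n)
    deg <- rowSums(S)
    H <- matrix(0, n, ncol(W[[r]]))
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) {
        if (S[i, j] > 0) {
          acc <- acc + S[i, j] / sqrt(deg[i] * deg[j]) * X[j, ]
        }
      }
      H[i, ] <- pmax(as.vector(acc %*% W[[r]]), 0)
    }
    out <- out + H
  }
  out
}

# exhaustive concordant-pair AUC oracle
auc_pair_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# small synthetic bundle for fast end-to-end tests
small_bundle <- function(seed = 2L) {
  generate_dataset(synthetic_config(n_drugs = 18L, n_targets = 24L,
                                    n_diseases = 40L, n_side_effects = 30L,
                                    seed = seed))
}

# fast configuration for smoke-level fits
fast_config <- function(seed = 1L, ...) {
  dti_config(n_kernels = 16L, d_hidden = 24L, d = 24L, K = 2L,
             epochs = 15L, patience = 15L, rf_ntree = 100L, seed = seed, ...)
}

# lazily computed expensive artefacts shared across acceptance tests
.acc_env <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (is.null(.acc_env$runs)) {
    runs <- lapply(1:3, function(s) {
      bundle <- generate_dataset(synthetic_config(seed = s))
      run_cv(bundle, dti_config(seed = s), mode = "random", k = 5L,
             max_folds = 1L)
    })
    .acc_env$runs <- runs
  }
  .acc_env$runs
}
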