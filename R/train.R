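# Joint end-to-end training of the sequence extractor and the graph
# encoder: full-batch Adam on the binary cross-entropy preference-matrix
# loss over a balanced sampled pair set, with early stopping on a
# held-out validation pair set.

# prefix helpers for the flat parameter list
.pv_subset <- function(pv, prefix) {
  nms <- names(pv)[startsWith(names(pv), prefix)]
  setNames(pv[nms], substring(nms, nchar(prefix) + 1L))
}

.cnn_flat <- function(params, prefix) {
  keep <- setdiff(names(params), c("C", "N", "n_blocks"))
  fl <- lapply(params[keep], function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L))
  setNames(fl, paste0(prefix, keep))
}

# assemble the training-ready data object
#
# net: hetnet; embs_drug / embs_prot: lists of seq_embedding in network
# node order; pairs: data.frame(drug, protein, y, w) of *balanced* training
# pairs (ids); val_pairs: unweighted validation pairs.
prepare_training_data <- function(net, embs_drug = NULL, embs_prot = NULL,
                                  train_pairs, val_pairs, config) {
  dv <- length(net$drug_ids); tv <- length(net$protein_ids)
  Y <- matrix(0, dv, tv, dimnames = list(net$drug_ids, net$protein_ids))
  Wt <- matrix(0, dv, tv)
  ia <- match(train_pairs$drug, net$drug_ids)
  ib <- match(train_pairs$protein, net$protein_ids)
  if (anyNA(ia) || anyNA(ib)) stop("training pair ids outside the network")
  for (row in seq_len(nrow(train_pairs))) {
    Wt[ia[row], ib[row]] <- Wt[ia[row], ib[row]] + train_pairs$w[row]
    Y[ia[row], ib[row]] <- train_pairs$y[row]
  }
  list(net = net,
       ahat = lapply(net$relations, normalized_adjacency),
       masks = lapply(net$relations, function(S) (S > 0) * 1),
       plan_drug = if (!is.null(embs_drug)) cnn_plan(embs_drug, config$n_blocks),
       plan_prot = if (!is.null(embs_prot)) cnn_plan(embs_prot, config$n_blocks),
       di = seq_len(dv), ti = dv + seq_len(tv),
       Y = Y, Wt = Wt, N = sum(Wt),
       val = list(i = match(val_pairs$drug, net$drug_ids),
                  j = match(val_pairs$protein, net$protein_ids),
                  y = val_pairs$y))
}

# single tape forward; returns loss adv plus embedding values
joint_forward <- function(flat, data, struct, cfg) {
  tape <- new_tape()
  pv <- lapply(flat, function(p) av_param(tape, p))
  if (cfg$use_cnn) {
    FD <- cnn_forward_ad(tape, .pv_subset(pv, "cd_"), data$plan_drug)
    FP <- cnn_forward_ad(tape, .pv_subset(pv, "cp_"), data$plan_prot)
    X0 <- av_concat_rows(FD, FP)
  } else {
    X0 <- av_const(tape, cfg$X0_random)
  }
  if (cfg$use_graph) {
    ahat_c <- lapply(data$ahat, function(A) av_const(tape, A))
    masks <- unname(data$masks)
    enc <- ad_encode_nodes(X0, pv, struct, unname(ahat_c), masks)
    X <- enc$X
  } else {
    X <- X0
  }
  XD <- av_rows(X, data$di)
  XT <- av_rows(X, data$ti)
  U <- av_matmul_t(XD, XT)
  loss <- av_bce_logits(U, data$Y, data$Wt, data$N)
  list(tape = tape, pv = pv, loss = loss, U = U, X = X, XD = XD, XT = XT)
}

#' Train the joint sequence + graph representation model
#'
#' Full-batch Adam on the weighted binary cross-entropy of the preference
#' matrix over the balanced training pairs; validation loss on held-out
#' pairs drives early stopping (patience in epochs); the best-validation
#' parameter set is returned. Deterministic given the seed.
#'
#' @param data Object from the fitting pipeline (network, sequence
#'   embeddings, pair sets); see [dti_fit()].
#' @param struct Encoder parameter structure ([init_encoder_params()]),
#'   or NULL when the graph stage is ablated.
#' @param cnn_drug,cnn_prot `cnn_params` for the two sequence extractors,
#'   or NULL when the biological-feature stage is ablated.
#' @param config Run configuration ([dti_config()]).
#' @return List: `flat` (trained parameters), `log` (data frame of
#'   epoch / train / validation loss), `best_epoch`.
#' @export
train_encoder <- function(data, struct, cnn_drug, cnn_prot, config) {
  cfg <- list(use_cnn = !is.null(cnn_drug), use_graph = !is.null(struct))
  flat <- list()
  if (cfg$use_cnn) {
    flat <- c(flat, .cnn_flat(cnn_drug, "cd_"), .cnn_flat(cnn_prot, "cp_"))
  } else {
    set.seed(config$seed + 101L)
    n <- length(data$net$ids)
    cfg$X0_random <- matrix(stats::rnorm(n * config$n_kernels), n,
                            config$n_kernels)
  }
  if (cfg$use_graph) flat <- c(flat, flatten_params(struct))
  if (length(flat) == 0L) stop("nothing to train: both stages ablated")

  opt <- adam_init(flat, lr = config$lr)
  log <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best <- list(val = Inf, flat = flat, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    fwd <- joint_forward(flat, data, struct, cfg)
    grads_by_id <- ad_backward(fwd$loss)
    grads <- lapply(fwd$pv, function(h) grads_by_id[[h$id]])
    tr <- av_value(fwd$loss)
    uv <- av_value(fwd$U)[cbind(data$val$i, data$val$j)]
    vl <- bce_loss(uv, data$val$y)
    log <- rbind(log, data.frame(epoch = ep, train = tr, val = vl))
    if (!is.finite(tr)) stop("training diverged (non-finite loss)")
    if (vl < best$val - 1e-6) {
      best <- list(val = vl, flat = flat, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    if (config$lr > 0) {
      st <- adam_step(opt, flat, grads)
      opt <- st$state
      flat <- st$params
    }
  }
  list(flat = best$flat, log = log, best_epoch = best$epoch, cfg = cfg)
}

# rebuild structured parameters and final embeddings from a training result
final_embeddings <- function(trained, data, struct) {
  fwd <- joint_forward(trained$flat, data, struct, trained$cfg)
  list(X_D = av_value(fwd$XD), X_T = av_value(fwd$XT))
}
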