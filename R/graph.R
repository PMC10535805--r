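# Relational graph encoder: per-relation symmetrically normalised graph
# convolutions and multi-head graph attention over the five typed
# relations of the heterogeneous network, stacked (default GCN-GAT-GCN)
# with a fusion layer combining the first- and third-layer outputs. The
# encoder is trained jointly with the sequence extractor by full-batch
# Adam on a binary cross-entropy loss over the preference matrix
# U = X_D X_T'.

#' Relational graph convolution step
#'
#' `X^{l+1} = sum_r relu( A_r^{-1/2} (I + S_r) A_r^{-1/2} X^l W_r )`,
#' summed over the five relations; a relation with no edges contributes
#' only its normalised self-loop term.
#'
#' @param X Node feature matrix (nodes x d_in), rows in network order.
#' @param net A `hetnet`.
#' @param W Named list of per-relation weight matrices (d_in x d_out),
#'   names as in `HETNET_RELATIONS`.
#' @return Matrix nodes x d_out.
#' @export
gcn_propagate <- function(X, net, W) {
  out <- NULL
  for (r in HETNET_RELATIONS) {
    if (ncol(X) != nrow(W[[r]])) stop("feature/weight dimension mismatch")
    H <- pmax(normalized_adjacency(net$relations[[r]]) %*% X %*% W[[r]], 0)
    out <- if (is.null(out)) H else out + H
  }
  out
}

#' Attention coefficients for one relation and head
#'
#' Additive attention: the logit for edge (i, j) under relation r is
#' `LeakyReLU( a' [W x_i || W x_j || B e_r] )`, row-normalised by a
#' softmax over i's r-neighbourhood. Rows without neighbours are zero.
#'
#' @param X Node features (nodes x d_in).
#' @param net A `hetnet`.
#' @param params A `gat_params` (see [init_gat_params()]).
#' @param r Relation name.
#' @param k Head index (1..K).
#' @return Matrix nodes x nodes; each row with >= 1 neighbour sums to 1.
#' @export
gat_attention <- function(X, net, params, r, k) {
  H <- X %*% params$W[[k]]
  dh <- ncol(H)
  a <- params$a[[k]]
  a1 <- a[seq_len(dh)]
  a2 <- a[dh + seq_len(dh)]
  a3 <- a[-seq_len(2L * dh)]
  cr <- sum(a3 * params$B[[k]][, match(r, HETNET_RELATIONS)])
  Z <- outer(as.vector(H %*% a1), as.vector(H %*% a2), "+") + cr
  Z <- ifelse(Z > 0, Z, params$slope * Z)
  M <- net$relations[[r]] > 0
  Zm <- ifelse(M, Z, -Inf)
  mx <- apply(Zm, 1L, max)
  mx[!is.finite(mx)] <- 0
  E <- exp(Zm - mx)
  E[!is.finite(E)] <- 0
  rs <- rowSums(E)
  E / ifelse(rs > 0, rs, 1)
}

#' Multi-head relational graph attention step
#'
#' `x_i^{l+1} = sum_r relu( (1/K) sum_k sum_j phi_r^{ijk} W_k x_j )`:
#' heads are averaged, relations summed; a node with no neighbours under
#' any relation maps to the zero vector.
#'
#' @inheritParams gat_attention
#' @return Matrix nodes x d_out.
#' @export
gat_propagate <- function(X, net, params) {
  out <- NULL
  for (r in HETNET_RELATIONS) {
    acc <- NULL
    for (k in seq_len(params$K)) {
      phi <- gat_attention(X, net, params, r, k)
      Hk <- phi %*% (X %*% params$W[[k]])
      acc <- if (is.null(acc)) Hk else acc + Hk
    }
    out_r <- pmax(acc / params$K, 0)
    out <- if (is.null(out)) out_r else out + out_r
  }
  out
}

#' Initialise GCN layer parameters
#' @param d_in,d_out Dimensions.
#' @param seed Integer seed.
#' @return Named list of per-relation weights, class `gcn_params`.
#' @export
init_gcn_params <- function(d_in, d_out, seed = 1L) {
  set.seed(seed)
  glorot <- function() matrix(stats::rnorm(d_in * d_out, 0,
                                           sqrt(2 / (d_in + d_out))),
                              d_in, d_out)
  structure(setNames(replicate(5, glorot(), simplify = FALSE),
                     HETNET_RELATIONS),
            class = "gcn_params")
}

#' Initialise GAT layer parameters
#' @param d_in,d_out Dimensions.
#' @param K Number of attention heads.
#' @param db Edge-type embedding width for the relation weights B.
#' @param slope Negative slope of the logit activation.
#' @param seed Integer seed.
#' @return Object of class `gat_params`.
#' @export
init_gat_params <- function(d_in, d_out, K = 4L, db = 8L, slope = 0.2,
                            seed = 1L) {
  set.seed(seed)
  glorot <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / (a + b))),
                                  a, b)
  structure(list(K = K, slope = slope,
                 W = replicate(K, glorot(d_in, d_out), simplify = FALSE),
                 a = replicate(K, stats::rnorm(2L * d_out + db, 0, 0.1),
                               simplify = FALSE),
                 B = replicate(K, glorot(db, 5L), simplify = FALSE)),
            class = "gat_params")
}

#' Encode all nodes and split into drug / target representations
#'
#' Applies the three graph layers in `layer_order` (default
#' GCN, GAT, GCN), then fuses the first- and third-layer outputs through
#' a learned linear map (window-1 convolution over the concatenated
#' features) and splits rows by node kind.
#'
#' @param X0 Initial node features (nodes x d_in), network row order.
#' @param net A `hetnet`.
#' @param params Encoder parameter set from [init_encoder_params()].
#' @return List `X_D` (drugs x d), `X_T` (proteins x d), `X`, and the
#'   per-layer outputs `X1`, `X2`, `X3`.
#' @export
encode_nodes <- function(X0, net, params) {
  Xs <- list()
  H <- X0
  for (l in seq_along(params$layer_order)) {
    ly <- params$layers[[l]]
    H <- if (params$layer_order[l] == "gcn") gcn_propagate(H, net, ly)
         else gat_propagate(H, net, ly)
    Xs[[l]] <- H
  }
  X <- sweep(cbind(Xs[[1L]], Xs[[3L]]) %*% params$fuse_W, 2L,
             params$fuse_b, "+")
  di <- which(net$kind == "drug")
  list(X_D = X[di, , drop = FALSE], X_T = X[-di, , drop = FALSE], X = X,
       X1 = Xs[[1L]], X2 = Xs[[2L]], X3 = Xs[[3L]])
}

#' Initialise the full graph encoder parameter set
#'
#' @param d_in Input feature dimension (sequence feature width).
#' @param d_hidden Width of every graph layer.
#' @param d Output embedding dimension.
#' @param K Attention heads.
#' @param db Edge-type embedding width.
#' @param layer_order Character vector of three layer types, default
#'   `c("gcn", "gat", "gcn")`; the alternative stack
#'   `c("gat", "gat", "gcn")` is supported.
#' @param seed Integer seed.
#' @return Object of class `encoder_params`.
#' @export
init_encoder_params <- function(d_in, d_hidden = 128L, d = 128L, K = 4L,
                                db = 8L,
                                layer_order = c("gcn", "gat", "gcn"),
                                seed = 1L) {
  stopifnot(length(layer_order) == 3L, all(layer_order %in% c("gcn", "gat")))
  set.seed(seed)
  dims_in <- c(d_in, d_hidden, d_hidden)
  layers <- vector("list", 3L)
  for (l in 1:3) {
    layers[[l]] <- if (layer_order[l] == "gcn") {
      init_gcn_params(dims_in[l], d_hidden, seed = seed + l)
    } else {
      init_gat_params(dims_in[l], d_hidden, K = K, db = db, seed = seed + l)
    }
  }
  set.seed(seed + 17L)
  structure(list(layer_order = layer_order, layers = layers,
                 fuse_W = matrix(stats::rnorm(2L * d_hidden * d, 0,
                                              sqrt(2 / (2 * d_hidden + d))),
                                 2L * d_hidden, d),
                 fuse_b = rep(0, d),
                 d_in = d_in, d_hidden = d_hidden, d = d, K = K, db = db),
            class = "encoder_params")
}

#' Binary cross-entropy over the preference matrix
#'
#' Scores are squashed through the logistic function and clamped at
#' `eps`; the loss is `-(1/N) sum [ y log u + (1 - y) log(1 - u) ]`,
#' optionally weighted per pair (duplicated resampled pairs carry
#' integer weights).
#'
#' @param U Raw score matrix or vector (inner products).
#' @param y 0/1 labels, same shape.
#' @param weights Optional non-negative weights, same shape.
#' @param eps Clamp for the squashed scores.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(U, y, weights = NULL, eps = 1e-7) {
  u <- pmin(pmax(stats::plogis(U), eps), 1 - eps)
  if (is.null(weights)) weights <- rep(1, length(u))
  N <- sum(weights)
  -sum(weights * (y * log(u) + (1 - y) * log(1 - u))) / N
}

# ---------------------------------------------------------------------------
# Flat parameter list <-> structured parameters, and the tape forward.

flatten_params <- function(struct) {
  out <- list()
  add <- function(prefix, x) {
    for (nm in names(x)) out[[paste0(prefix, nm)]] <<- x[[nm]]
  }
  for (l in seq_along(struct$layer_order)) {
    pre <- paste0("g", l, "_")
    ly <- struct$layers[[l]]
    if (struct$layer_order[l] == "gcn") {
      add(pre, setNames(ly[HETNET_RELATIONS], paste0("W_", seq_len(5L))))
    } else {
      for (k in seq_len(ly$K)) {
        out[[paste0(pre, "W", k)]] <- ly$W[[k]]
        out[[paste0(pre, "a", k)]] <- matrix(ly$a[[k]], ncol = 1L)
        out[[paste0(pre, "B", k)]] <- ly$B[[k]]
      }
    }
  }
  out$fuse_W <- struct$fuse_W
  out$fuse_b <- struct$fuse_b
  out
}

unflatten_params <- function(flat, struct) {
  for (l in seq_along(struct$layer_order)) {
    pre <- paste0("g", l, "_")
    if (struct$layer_order[l] == "gcn") {
      for (i in seq_len(5L)) {
        struct$layers[[l]][[HETNET_RELATIONS[i]]] <-
          flat[[paste0(pre, "W_", i)]]
      }
    } else {
      for (k in seq_len(struct$layers[[l]]$K)) {
        struct$layers[[l]]$W[[k]] <- flat[[paste0(pre, "W", k)]]
        struct$layers[[l]]$a[[k]] <- as.vector(flat[[paste0(pre, "a", k)]])
        struct$layers[[l]]$B[[k]] <- flat[[paste0(pre, "B", k)]]
      }
    }
  }
  struct$fuse_W <- flat$fuse_W
  struct$fuse_b <- as.vector(flat$fuse_b)
  struct
}

# one GCN layer on the tape
ad_gcn_layer <- function(Xadv, pv, pre, ahat_consts) {
  out <- NULL
  for (i in seq_len(5L)) {
    H <- av_relu(av_matmul(ahat_consts[[i]],
                           av_matmul(Xadv, pv[[paste0(pre, "W_", i)]])))
    out <- if (is.null(out)) H else av_add(out, H)
  }
  out
}

# one GAT layer on the tape
ad_gat_layer <- function(Xadv, pv, pre, masks, K, slope) {
  out <- NULL
  for (r in seq_len(5L)) {
    acc <- NULL
    for (k in seq_len(K)) {
      Wk <- pv[[paste0(pre, "W", k)]]
      ak <- pv[[paste0(pre, "a", k)]]
      Bk <- pv[[paste0(pre, "B", k)]]
      H <- av_matmul(Xadv, Wk)
      dh <- ncol(av_value(H))
      a1 <- av_rows(ak, seq_len(dh))
      a2 <- av_rows(ak, dh + seq_len(dh))
      a3 <- av_rows(ak, 2L * dh + seq_len(nrow(av_value(ak)) - 2L * dh))
      s1 <- av_matmul(H, a1)
      s2 <- av_matmul(H, a2)
      cr <- av_pick(av_matmul(av_transpose(a3), Bk), 1L, r)
      Z <- av_lrelu(av_addscalar(av_outer_sum(s1, s2), cr), slope)
      phi <- av_masked_softmax_rows(Z, masks[[r]])
      Hk <- av_matmul(phi, H)
      acc <- if (is.null(acc)) Hk else av_add(acc, Hk)
    }
    out_r <- av_relu(av_scale(acc, 1 / K))
    out <- if (is.null(out)) out_r else av_add(out, out_r)
  }
  out
}

# full encoder forward on the tape; returns list(X1, X3, X)
ad_encode_nodes <- function(Xadv, pv, struct, ahat_consts, masks) {
  Xs <- list()
  H <- Xadv
  for (l in seq_along(struct$layer_order)) {
    pre <- paste0("g", l, "_")
    H <- if (struct$layer_order[l] == "gcn") {
      ad_gcn_layer(H, pv, pre, ahat_consts)
    } else {
      ly <- struct$layers[[l]]
      ad_gat_layer(H, pv, pre, masks, ly$K, ly$slope)
    }
    Xs[[l]] <- H
  }
  X <- av_addbias(av_matmul(av_concat_cols(Xs[[1L]], Xs[[3L]]), pv$fuse_W),
                  pv$fuse_b)
  list(X1 = Xs[[1L]], X3 = Xs[[3L]], X = X)
}
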