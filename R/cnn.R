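# Convolutional sequence feature extractor. A one-hot channel-by-length
# embedding passes through (1) a linear window-3 "region" convolution with
# N kernels, (2) two window-3 refinement convolutions that rectify their
# input before the cross-channel weighted sum, and (3) residual
# aggregation blocks X_{t+1} = P(X_t) + theta(P(X_t)) where P is stride-2
# max pooling and theta is a two-convolution map (same padding), halving
# the sequence length per block. A global max over valid (unmasked)
# positions reads out a fixed-length feature vector per sequence.
#
# All convolutions here use window 3 and "valid" extent except inside
# theta, which uses zero same-padding so its output can be added to the
# pooled input. Position masks are carried through every stage so padding
# never leaks into the feature vector.

#' Initialise extractor parameters
#'
#' He-style normal initialisation, seeded.
#'
#' @param C Input channel count (vocabulary size).
#' @param N Number of kernels / feature channels (default 64).
#' @param n_blocks Number of aggregation blocks (default 2).
#' @param seed Integer seed.
#' @return Named list of weight/bias matrices of class `cnn_params`.
#' @export
init_cnn_params <- function(C, N = 64L, n_blocks = 2L, seed = 1L) {
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  p <- list(W1 = he(3L * C, N), b1 = rep(0, N),
            W2 = he(3L * N, N), b2 = rep(0, N),
            W3 = he(3L * N, N), b3 = rep(0, N))
  for (t in seq_len(n_blocks)) {
    p[[paste0("Wa", t)]] <- he(3L * N, N)
    p[[paste0("ba", t)]] <- rep(0, N)
    p[[paste0("Wb", t)]] <- he(3L * N, N)
    p[[paste0("bb", t)]] <- rep(0, N)
  }
  structure(c(p, list(C = C, N = N, n_blocks = n_blocks)), class = "cnn_params")
}

# window-3 valid im2col of a positions-by-channels matrix
.im2col3 <- function(X) {
  L <- nrow(X)
  stopifnot(L >= 3L)
  p <- seq_len(L - 2L)
  cbind(X[p, , drop = FALSE], X[p + 1L, , drop = FALSE], X[p + 2L, , drop = FALSE])
}

# window-3 same-padding im2col (zero rows beyond the ends)
.im2col3_same <- function(X) {
  Z <- rbind(0, X, 0)
  L <- nrow(X)
  p <- seq_len(L)
  cbind(Z[p, , drop = FALSE], Z[p + 1L, , drop = FALSE], Z[p + 2L, , drop = FALSE])
}

#' Region embedding convolution
#'
#' Linear window-3 valid convolution of the one-hot embedding with N
#' kernels (no nonlinearity); column i of the output is kernel i's
#' response, length `L - 2`.
#'
#' @param X A `seq_embedding` or a dense `C x L` numeric matrix.
#' @param W Weight matrix `(3C) x N` (rows ordered window-offset-major:
#'   offsets 1..3, each block of C channels).
#' @param b Bias vector length N.
#' @return Numeric matrix `(L - 2) x N`.
#' @export
region_embed <- function(X, W, b = NULL) {
  if (inherits(X, "seq_embedding")) X <- as.matrix(X)
  if (nrow(X) * 3L != nrow(W)) stop("weight shape does not match channels")
  if (ncol(X) < 3L) stop("sequence length < 3: window-3 convolution undefined")
  M <- .im2col3(t(X))
  out <- M %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  out
}

#' Refinement convolution
#'
#' Rectifies the input channels, then applies a window-3 valid
#' cross-channel convolution with N kernels (weighted channel sum), plus
#' bias. No activation follows the sum.
#'
#' @param X Numeric matrix `L x N_in` (positions by channels).
#' @param W Weight matrix `(3 N_in) x N`.
#' @param b Bias vector length N.
#' @return Numeric matrix `(L - 2) x N`.
#' @export
conv_refine <- function(X, W, b = NULL) {
  if (nrow(X) < 3L) stop("input length < 3")
  if (ncol(X) * 3L != nrow(W)) stop("weight shape does not match channels")
  M <- .im2col3(pmax(X, 0))
  out <- M %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  out
}

#' Residual aggregation block
#'
#' `X_{t+1} = P(X_t) + theta(P(X_t))`: stride-2 max pooling P halves the
#' length (floor), then a two-convolution map theta (same padding;
#' conv -> rectifier -> conv) is added back.
#'
#' @param X Numeric matrix `L x N`, `L >= 2`.
#' @param Wa,ba,Wb,bb The two convolution parameter sets of theta
#'   (`(3N) x N` weights, length-N biases). When all are zero, the block
#'   reduces to plain max pooling.
#' @param valid Number of leading valid (unmasked) rows of `X`; rows of
#'   the output beyond `floor(valid / 2)` are zeroed at every internal
#'   stage so padding never contaminates valid positions.
#' @return Numeric matrix `floor(L / 2) x N`.
#' @export
aggregate_block <- function(X, Wa, ba, Wb, bb, valid = nrow(X)) {
  L <- nrow(X)
  if (L < 2L) stop("input length < 2: cannot pool")
  np <- L %/% 2L
  vp <- min(np, valid %/% 2L)
  i1 <- 2L * seq_len(np) - 1L
  P <- pmax(X[i1, , drop = FALSE], X[i1 + 1L, , drop = FALSE])
  P[seq_len(np) > vp, ] <- 0
  T1 <- sweep(.im2col3_same(P) %*% Wa, 2L, ba, "+")
  T1[seq_len(np) > vp, ] <- 0
  T2 <- sweep(.im2col3_same(pmax(T1, 0)) %*% Wb, 2L, bb, "+")
  out <- P + T2
  out[seq_len(np) > vp, ] <- 0
  out
}

# valid-length bookkeeping through the stack; errors if any sequence
# would lose all positions
.cnn_valid_lengths <- function(v, n_blocks, id = NULL) {
  v <- v - 6L                       # region + two refinement convolutions
  for (t in seq_len(n_blocks)) v <- v %/% 2L
  if (any(v < 1L)) {
    stop(sprintf(
      "sequence%s too short for the extractor depth (needs >= %d tokens)",
      if (is.null(id)) "(s)" else paste0(" '", id, "'"),
      .cnn_min_tokens(n_blocks)))
  }
  v
}

#' Minimum token count the extractor can consume
#' @param n_blocks Number of aggregation blocks.
#' @return Integer.
#' @export
.cnn_min_tokens <- function(n_blocks = 2L) 6L + 2L^n_blocks

#' Extract a fixed-length feature vector from a sequence embedding
#'
#' Composition: region convolution, two refinement convolutions, then the
#' aggregation blocks, then a global max over valid positions. Padded
#' positions are masked at every stage, so the result is independent of
#' the padded length.
#'
#' @param X A `seq_embedding`.
#' @param params A `cnn_params` whose `C` matches the embedding.
#' @return Numeric feature vector of length `params$N`.
#' @export
extract_features <- function(X, params) {
  stopifnot(inherits(X, "seq_embedding"), inherits(params, "cnn_params"),
            params$C == X$C)
  v <- X$n_valid
  .cnn_valid_lengths(v, params$n_blocks, X$id)
  M <- as.matrix(X)
  H <- region_embed(M, params$W1, params$b1)
  v <- v - 2L; H[seq_len(nrow(H)) > v, ] <- 0
  H <- conv_refine(H, params$W2, params$b2)
  v <- v - 2L; H[seq_len(nrow(H)) > v, ] <- 0
  H <- conv_refine(H, params$W3, params$b3)
  v <- v - 2L; H[seq_len(nrow(H)) > v, ] <- 0
  for (t in seq_len(params$n_blocks)) {
    H <- aggregate_block(H, params[[paste0("Wa", t)]], params[[paste0("ba", t)]],
                         params[[paste0("Wb", t)]], params[[paste0("bb", t)]],
                         valid = v)
    v <- v %/% 2L
  }
  apply(H[seq_len(v), , drop = FALSE], 2L, max)
}

# ---------------------------------------------------------------------------
# Batched autodiff path: all sequences of one kind are laid out as stacked
# position rows so each layer is a single gather + matmul on the tape.

# Precompute gather indices, masks and final pooling groups for a batch of
# embeddings (all sharing C and L).
cnn_plan <- function(embs, n_blocks = 2L) {
  S <- length(embs)
  L <- embs[[1L]]$L
  C <- embs[[1L]]$C
  stopifnot(all(vapply(embs, function(e) e$L == L && e$C == C, TRUE)))
  v0 <- vapply(embs, function(e) e$n_valid, 1L)
  .cnn_valid_lengths(v0, n_blocks)

  L1 <- L - 2L
  # layer 1: window-3 one-hot convolution as three embedding lookups into
  # the (3C) x N weight table; padded positions point at row 1, mask 0
  tok <- matrix(1L, S, L)
  for (s in seq_len(S)) tok[s, seq_len(v0[s])] <- embs[[s]]$token_idx + 1L
  p <- seq_len(L1)
  i1 <- as.vector(t(tok[, p, drop = FALSE]))
  i2 <- as.vector(t(tok[, p + 1L, drop = FALSE])) + C
  i3 <- as.vector(t(tok[, p + 2L, drop = FALSE])) + 2L * C

  vmask <- function(v, Lk) as.vector(vapply(seq_len(S), function(s)
    as.numeric(seq_len(Lk) <= v[s]), numeric(Lk)))
  gidx_valid <- function(Lin, Lout) {
    base <- rep((seq_len(S) - 1L) * Lin, each = Lout)
    pp <- rep(seq_len(Lout), S)
    list(base + pp, base + pp + 1L, base + pp + 2L)
  }
  # same-padding gather with a single trailing zero row (index nrow+1)
  gidx_same <- function(Lk) {
    zr <- S * Lk + 1L
    base <- rep((seq_len(S) - 1L) * Lk, each = Lk)
    pp <- rep(seq_len(Lk), S)
    left <- base + pp - 1L; left[pp == 1L] <- zr
    right <- base + pp + 1L; right[pp == Lk] <- zr
    list(left, base + pp, right)
  }

  v1 <- v0 - 2L
  L2 <- L1 - 2L; v2 <- v1 - 2L
  L3 <- L2 - 2L; v3 <- v2 - 2L
  plan <- list(S = S, C = C, L = L, n_blocks = n_blocks,
               emb_idx = list(i1, i2, i3),
               m1 = vmask(v1, L1),
               g2 = gidx_valid(L1, L2), m2 = vmask(v2, L2),
               g3 = gidx_valid(L2, L3), m3 = vmask(v3, L3))
  Lk <- L3; vk <- v3
  for (t in seq_len(n_blocks)) {
    np <- Lk %/% 2L
    i_odd <- as.vector(vapply(seq_len(S), function(s)
      (s - 1L) * Lk + 2L * seq_len(np) - 1L, integer(np)))
    plan[[paste0("pool", t)]] <- list(i_odd, i_odd + 1L)
    vk <- vk %/% 2L
    Lk <- np
    plan[[paste0("gs", t)]] <- gidx_same(Lk)
    plan[[paste0("mblk", t)]] <- vmask(vk, Lk)
  }
  # final global max over valid rows only
  keep <- which(plan[[paste0("mblk", n_blocks)]] > 0)
  plan$final_rows <- keep
  plan$final_groups <- ((keep - 1L) %/% Lk) + 1L
  plan
}

# forward pass on the tape; pv = list of adv parameter handles named as in
# init_cnn_params; returns an S x N adv of feature vectors
cnn_forward_ad <- function(tape, pv, plan) {
  H <- av_embed3(pv$W1, plan$emb_idx[[1L]], plan$emb_idx[[2L]], plan$emb_idx[[3L]])
  H <- av_addbias(H, pv$b1)
  H <- av_mask(H, plan$m1)
  for (ly in list(list("W2", "b2", "g2", "m2"), list("W3", "b3", "g3", "m3"))) {
    R <- av_relu(H)
    G <- plan[[ly[[3L]]]]
    H <- av_conv3(R, G[[1L]], G[[2L]], G[[3L]], pv[[ly[[1L]]]])
    H <- av_addbias(H, pv[[ly[[2L]]]])
    H <- av_mask(H, plan[[ly[[4L]]]])
  }
  for (t in seq_len(plan$n_blocks)) {
    pool <- plan[[paste0("pool", t)]]
    mb <- plan[[paste0("mblk", t)]]
    P <- av_mask(av_rowpairs_max(H, pool[[1L]], pool[[2L]]), mb)
    gs <- plan[[paste0("gs", t)]]
    Pp <- av_pad_zero_row(P)
    T1 <- av_addbias(av_conv3(Pp, gs[[1L]], gs[[2L]], gs[[3L]],
                              pv[[paste0("Wa", t)]]),
                     pv[[paste0("ba", t)]])
    T1p <- av_pad_zero_row(av_relu(av_mask(T1, mb)))
    T2 <- av_addbias(av_conv3(T1p, gs[[1L]], gs[[2L]], gs[[3L]],
                              pv[[paste0("Wb", t)]]),
                     pv[[paste0("bb", t)]])
    H <- av_mask(av_add(P, T2), mb)
  }
  av_groupmax(av_rows(H, plan$final_rows), plan$final_groups)
}
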