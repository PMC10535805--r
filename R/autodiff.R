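# Minimal tape-based reverse-mode automatic differentiation on dense
# matrices. Only the operations needed by the sequence extractor and the
# relational graph encoder are provided; every op appends one node to a
# topologically ordered tape, so a single reverse sweep yields exact
# gradients for all parameters.
#
# A value on the tape is addressed by an `adv` handle (tape + node id).
# Backward closures receive the upstream gradient and return a list of
# gradients aligned with the node's parents (NULL = no gradient).

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$nodes <- vector("list", 256L)
  e
}

.tape_push <- function(tape, val, parents = integer(0), backward = NULL) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- list(val = val, parents = parents, backward = backward)
  structure(list(tape = tape, id = tape$n), class = "adv")
}

av_value <- function(x) x$tape$nodes[[x$id]]$val

#' @noRd
av_const <- function(tape, val) .tape_push(tape, val)

# Parameters are leaves like constants; callers keep the ids to read
# gradients back after the reverse sweep.
av_param <- function(tape, val) .tape_push(tape, val)

av_matmul <- function(a, b) {
  A <- av_value(a); B <- av_value(b)
  .tape_push(a$tape, A %*% B, c(a$id, b$id),
             function(g) list(g %*% t(B), crossprod(A, g)))
}

# A %*% t(B) without materialising the transpose on the tape
av_matmul_t <- function(a, b) {
  A <- av_value(a); B <- av_value(b)
  .tape_push(a$tape, tcrossprod(A, B), c(a$id, b$id),
             function(g) list(g %*% B, crossprod(g, A)))
}

av_add <- function(a, b) {
  .tape_push(a$tape, av_value(a) + av_value(b), c(a$id, b$id),
             function(g) list(g, g))
}

# add a length-ncol bias vector to every row
av_addbias <- function(a, b) {
  A <- av_value(a); v <- av_value(b)
  .tape_push(a$tape, sweep(A, 2L, v, "+"), c(a$id, b$id),
             function(g) list(g, colSums(g)))
}

# add an adv scalar to every entry
av_addscalar <- function(a, s) {
  .tape_push(a$tape, av_value(a) + as.numeric(av_value(s)), c(a$id, s$id),
             function(g) list(g, sum(g)))
}

av_scale <- function(a, s) {
  .tape_push(a$tape, av_value(a) * s, a$id, function(g) list(g * s))
}

av_relu <- function(a) {
  A <- av_value(a)
  .tape_push(a$tape, pmax(A, 0), a$id, function(g) list(g * (A > 0)))
}

av_lrelu <- function(a, slope = 0.2) {
  A <- av_value(a)
  pos <- A > 0
  .tape_push(a$tape, A * (pos + slope * !pos), a$id,
             function(g) list(g * (pos + slope * !pos)))
}

# elementwise multiply by a constant matrix/vector (vectors recycle down
# rows, i.e. act as a per-row mask)
av_mask <- function(a, m) {
  .tape_push(a$tape, av_value(a) * m, a$id, function(g) list(g * m))
}

av_transpose <- function(a) {
  .tape_push(a$tape, t(av_value(a)), a$id, function(g) list(t(g)))
}

# single entry as a 1x1 value
av_pick <- function(a, i, j) {
  A <- av_value(a)
  .tape_push(a$tape, A[i, j, drop = FALSE], a$id,
             function(g) {
               out <- A * 0
               out[i, j] <- as.numeric(g)
               list(out)
             })
}

av_concat_rows <- function(a, b) {
  A <- av_value(a); B <- av_value(b)
  na <- nrow(A)
  .tape_push(a$tape, rbind(A, B), c(a$id, b$id),
             function(g) list(g[seq_len(na), , drop = FALSE],
                              g[-seq_len(na), , drop = FALSE]))
}

av_concat_cols <- function(a, b) {
  A <- av_value(a); B <- av_value(b)
  na <- ncol(A)
  .tape_push(a$tape, cbind(A, B), c(a$id, b$id),
             function(g) list(g[, seq_len(na), drop = FALSE],
                              g[, -seq_len(na), drop = FALSE]))
}

# scatter-add rows of g into a zero matrix of nr rows, grouped by idx
.scatter_rows <- function(g, idx, nr) {
  out <- matrix(0, nr, ncol(g))
  agg <- rowsum(g, idx, reorder = FALSE)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

av_rows <- function(a, idx) {
  A <- av_value(a)
  nr <- nrow(A)
  .tape_push(a$tape, A[idx, , drop = FALSE], a$id,
             function(g) list(.scatter_rows(g, idx, nr)))
}

# fused window-3 convolution: A[i1,] W1 + A[i2,] W2 + A[i3,] W3 with the
# (3C) x N weight table W split by window offset. Avoids materialising the
# im2col gather. Each index vector must reference any real row at most
# once; duplicated indices are permitted only at a row whose gradient the
# caller discards (the zero padding row appended by av_pad_zero_row).
av_conv3 <- function(a, i1, i2, i3, w) {
  A <- av_value(a); W <- av_value(w)
  nc <- ncol(A); nr <- nrow(A)
  s <- seq_len(nc)
  W1 <- W[s, , drop = FALSE]
  W2 <- W[nc + s, , drop = FALSE]
  W3 <- W[2L * nc + s, , drop = FALSE]
  A1 <- A[i1, , drop = FALSE]
  A2 <- A[i2, , drop = FALSE]
  A3 <- A[i3, , drop = FALSE]
  .tape_push(a$tape, A1 %*% W1 + A2 %*% W2 + A3 %*% W3, c(a$id, w$id),
             function(g) {
               gA <- matrix(0, nr, nc)
               gA[i1, ] <- gA[i1, , drop = FALSE] + tcrossprod(g, W1)
               gA[i2, ] <- gA[i2, , drop = FALSE] + tcrossprod(g, W2)
               gA[i3, ] <- gA[i3, , drop = FALSE] + tcrossprod(g, W3)
               gW <- rbind(crossprod(A1, g), crossprod(A2, g),
                           crossprod(A3, g))
               list(gA, gW)
             })
}

# cbind(A[i1,], A[i2,], A[i3,]) -- the window-3 im2col gather
av_gather3 <- function(a, i1, i2, i3) {
  A <- av_value(a)
  nr <- nrow(A); nc <- ncol(A)
  .tape_push(a$tape, cbind(A[i1, , drop = FALSE],
                           A[i2, , drop = FALSE],
                           A[i3, , drop = FALSE]),
             a$id,
             function(g) {
               s1 <- seq_len(nc)
               list(.scatter_rows(g[, s1, drop = FALSE], i1, nr) +
                    .scatter_rows(g[, nc + s1, drop = FALSE], i2, nr) +
                    .scatter_rows(g[, 2L * nc + s1, drop = FALSE], i3, nr))
             })
}

# W[i1,] + W[i2,] + W[i3,]: window-3 convolution of a one-hot sequence as
# three embedding-table lookups (indices carry the window-offset shift)
av_embed3 <- function(w, i1, i2, i3) {
  W <- av_value(w)
  nr <- nrow(W)
  .tape_push(w$tape,
             W[i1, , drop = FALSE] + W[i2, , drop = FALSE] + W[i3, , drop = FALSE],
             w$id,
             function(g) list(.scatter_rows(g, i1, nr) +
                              .scatter_rows(g, i2, nr) +
                              .scatter_rows(g, i3, nr)))
}

# pmax of two row selections: stride-2 max pooling along the sequence axis
av_rowpairs_max <- function(a, i1, i2) {
  A <- av_value(a)
  nr <- nrow(A)
  X1 <- A[i1, , drop = FALSE]; X2 <- A[i2, , drop = FALSE]
  sel <- X1 >= X2   # ties routed to the first element
  .tape_push(a$tape, pmax(X1, X2), a$id,
             function(g) list(.scatter_rows(g * sel, i1, nr) +
                              .scatter_rows(g * !sel, i2, nr)))
}

# per-group, per-column max (global max pooling over valid positions);
# groups must be a vector of consecutive integers 1..G
av_groupmax <- function(a, groups) {
  A <- av_value(a)
  G <- max(groups)
  nc <- ncol(A); nr <- nrow(A)
  val <- matrix(-Inf, G, nc)
  arg <- matrix(NA_integer_, G, nc)
  rows_by_g <- split(seq_len(nr), groups)
  for (g_i in seq_len(G)) {
    rows <- rows_by_g[[g_i]]
    sub <- A[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    arg[g_i, ] <- rows[am]
    val[g_i, ] <- sub[cbind(am, seq_len(nc))]
  }
  .tape_push(a$tape, val, a$id,
             function(g) {
               out <- matrix(0, nr, nc)
               idx <- cbind(as.vector(arg), rep(seq_len(nc), each = G))
               out[idx] <- as.vector(g)   # argmax rows are distinct per group
               list(out)
             })
}

# append one all-zero row (lets same-padding convolutions index "past the
# end" safely)
av_pad_zero_row <- function(a) {
  A <- av_value(a)
  .tape_push(a$tape, rbind(A, 0), a$id,
             function(g) list(g[-nrow(g), , drop = FALSE]))
}

# s1 %*% 1' + 1 %*% s2': all pairwise sums of two column vectors (the
# additive attention logit layout)
av_outer_sum <- function(s1, s2) {
  v1 <- as.vector(av_value(s1)); v2 <- as.vector(av_value(s2))
  .tape_push(s1$tape, outer(v1, v2, "+"), c(s1$id, s2$id),
             function(g) list(matrix(rowSums(g), ncol = 1),
                              matrix(colSums(g), ncol = 1)))
}

# row-wise softmax restricted to mask == 1 entries; fully masked rows
# yield all-zero rows
av_masked_softmax_rows <- function(a, mask) {
  Z <- av_value(a)
  Zm <- Z
  Zm[mask <= 0] <- -Inf
  mx <- apply(Zm, 1L, max)
  mx[!is.finite(mx)] <- 0
  E <- exp(Zm - mx)
  E[!is.finite(E)] <- 0
  rs <- rowSums(E)
  S <- E / ifelse(rs > 0, rs, 1)
  .tape_push(a$tape, S, a$id,
             function(g) {
               gz <- S * (g - rowSums(g * S))
               list(gz)
             })
}

# mean binary cross-entropy of logits U against labels Y with per-cell
# weights W (duplicate sampled pairs carry integer weights); N = total
# number of weighted pairs
av_bce_logits <- function(u, Y, W, N) {
  U <- av_value(u)
  P <- stats::plogis(U)
  eps <- 1e-7
  Pc <- pmin(pmax(P, eps), 1 - eps)
  loss <- -sum(W * (Y * log(Pc) + (1 - Y) * log(1 - Pc))) / N
  .tape_push(u$tape, loss, u$id,
             function(g) list(g * W * (P - Y) / N))
}

# reverse sweep; returns the list of gradients indexed by node id
ad_backward <- function(loss) {
  tape <- loss$tape
  n <- tape$n
  grads <- vector("list", n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[j]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# Adam optimiser state over a flat named list of parameter matrices
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / corr1) /
        (sqrt(state$v[[nm]] / corr2) + state$eps)
  }
  list(state = state, params = params)
}
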