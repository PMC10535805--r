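# Reverse-mode engine: every composite gradient is checked against
# central differences at unsaturated operating points.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("matmul / relu / bias / concat / rows chain gradients are exact", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3) * 0.5
  W <- matrix(rnorm(6), 3, 2) * 0.5
  b <- rnorm(2) * 0.1
  Y <- matrix(rbinom(4, 1, 0.5), 2, 2)
  f <- function(w) {
    tape <- hetdti:::new_tape()
    wv <- hetdti:::av_param(tape, matrix(w, 3, 2))
    bv <- hetdti:::av_param(tape, b)
    xv <- hetdti:::av_const(tape, X)
    H <- hetdti:::av_relu(hetdti:::av_addbias(hetdti:::av_matmul(xv, wv), bv))
    Hc <- hetdti:::av_concat_cols(H, H)
    U <- hetdti:::av_matmul_t(hetdti:::av_rows(Hc, 1:2),
                              hetdti:::av_rows(Hc, 3:4))
    hetdti:::av_value(hetdti:::av_bce_logits(U, Y, Y * 0 + 1, 4))
  }
  tape <- hetdti:::new_tape()
  wv <- hetdti:::av_param(tape, W)
  bv <- hetdti:::av_param(tape, b)
  xv <- hetdti:::av_const(tape, X)
  H <- hetdti:::av_relu(hetdti:::av_addbias(hetdti:::av_matmul(xv, wv), bv))
  Hc <- hetdti:::av_concat_cols(H, H)
  U <- hetdti:::av_matmul_t(hetdti:::av_rows(Hc, 1:2), hetdti:::av_rows(Hc, 3:4))
  loss <- hetdti:::av_bce_logits(U, Y, Y * 0 + 1, 4)
  g <- hetdti:::ad_backward(loss)
  expect_equal(as.vector(g[[wv$id]]), as.vector(num_grad(f, as.vector(W))),
               tolerance = 1e-6)
})

test_that("pooling, group-max, masked softmax and conv3 gradients are exact", {
  set.seed(2)
  X <- matrix(rnorm(10 * 3), 10, 3) * 0.4
  W <- matrix(rnorm(9 * 3), 9, 3) * 0.4
  M <- matrix(rbinom(9, 1, 0.6), 3, 3); diag(M) <- 0
  groups <- rep(1:2, c(2, 2))
  make <- function(Xm, Wm) {
    tape <- hetdti:::new_tape()
    xv <- hetdti:::av_param(tape, Xm)
    wv <- hetdti:::av_param(tape, Wm)
    C <- hetdti:::av_conv3(xv, 1:8, 2:9, 3:10, wv)       # valid conv, 8 rows
    P <- hetdti:::av_rowpairs_max(C, c(1, 3, 5, 7), c(2, 4, 6, 8))
    G <- hetdti:::av_groupmax(P, groups)                  # 2 x 3
    sm <- hetdti:::av_masked_softmax_rows(
      hetdti:::av_lrelu(hetdti:::av_matmul_t(G, G), 0.2) , M[1:2, 1:2])
    out <- hetdti:::av_matmul(sm, G)
    loss <- hetdti:::av_bce_logits(out, matrix(c(1, 0, 0, 1, 1, 0), 2, 3),
                                   matrix(1, 2, 3), 6)
    list(tape = tape, loss = loss, xv = xv, wv = wv)
  }
  o <- make(X, W)
  g <- hetdti:::ad_backward(o$loss)
  fx <- function(x) hetdti:::av_value(make(matrix(x, 10, 3), W)$loss)
  fw <- function(w) hetdti:::av_value(make(X, matrix(w, 9, 3))$loss)
  expect_equal(as.vector(g[[o$xv$id]]), as.vector(num_grad(fx, as.vector(X))),
               tolerance = 1e-5)
  expect_equal(as.vector(g[[o$wv$id]]), as.vector(num_grad(fw, as.vector(W))),
               tolerance = 1e-5)
})

test_that("embedding-lookup convolution gradient matches scatter oracle", {
  set.seed(3)
  W <- matrix(rnorm(9 * 2), 9, 2) * 0.5
  i1 <- c(1, 2, 3); i2 <- c(4, 5, 4); i3 <- c(7, 8, 9)
  f <- function(w) {
    tape <- hetdti:::new_tape()
    wv <- hetdti:::av_param(tape, matrix(w, 9, 2))
    H <- hetdti:::av_embed3(wv, i1, i2, i3)
    hetdti:::av_value(hetdti:::av_bce_logits(H, matrix(c(1, 0, 1, 0, 1, 0), 3, 2),
                                             matrix(1, 3, 2), 6))
  }
  tape <- hetdti:::new_tape()
  wv <- hetdti:::av_param(tape, W)
  H <- hetdti:::av_embed3(wv, i1, i2, i3)
  loss <- hetdti:::av_bce_logits(H, matrix(c(1, 0, 1, 0, 1, 0), 3, 2),
                                 matrix(1, 3, 2), 6)
  g <- hetdti:::ad_backward(loss)
  expect_equal(as.vector(g[[wv$id]]), as.vector(num_grad(f, as.vector(W))),
               tolerance = 1e-6)
})

test_that("Adam updates move parameters and zero learning rate does not", {
  p <- list(w = matrix(1, 2, 2))
  g <- list(w = matrix(0.5, 2, 2))
  st <- hetdti:::adam_init(p, lr = 0.1)
  out <- hetdti:::adam_step(st, p, g)
  expect_true(all(out$params$w < 1))
  st0 <- hetdti:::adam_init(p, lr = 0)
  out0 <- hetdti:::adam_step(st0, p, g)
  expect_equal(out0$params$w, p$w)
})
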