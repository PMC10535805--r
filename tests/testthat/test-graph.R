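# Relational GCN/GAT encoder: propagation oracles, attention
# normalization, fusion wiring, equivariance, loss values and the
# training loop contracts.

test_that("graph convolution matches the per-node loop oracle", {
  for (seed in 1:20) {
    net <- tiny_hetnet(seed = seed, n_d = 5L, n_p = 5L)
    set.seed(seed + 100)
    X <- matrix(rnorm(10 * 3), 10, 3)
    W <- init_gcn_params(3, 4, seed = seed)
    expect_equal(gcn_propagate(X, net, W), gcn_loop_oracle(X, net, W),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("graph convolution worked examples hold", {
  # two nodes joined by one edge, x = (1, 0), identity weight -> both 0.5
  Ah <- hetdti:::normalized_adjacency(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(as.vector(Ah %*% c(1, 0)), c(0.5, 0.5))
  # zeroing one relation's weight removes exactly its contribution
  net <- tiny_hetnet(seed = 5)
  set.seed(5)
  X <- matrix(abs(rnorm(9 * 2)), 9, 2)
  W <- init_gcn_params(2, 3, seed = 5)
  full <- gcn_propagate(X, net, W)
  W0 <- W; W0$drug_drug_interaction[] <- 0
  dropped <- gcn_propagate(X, net, W0)
  manual <- full - pmax(hetdti:::normalized_adjacency(
    net$relations$drug_drug_interaction) %*% X %*% W$drug_drug_interaction, 0)
  expect_equal(dropped, manual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("attention coefficients are softmax-normalised over neighbourhoods", {
  net <- tiny_hetnet(seed = 7)
  set.seed(7)
  X <- matrix(rnorm(9 * 3), 9, 3)
  par <- init_gat_params(3, 4, K = 2, db = 2, seed = 7)
  for (r in hetdti:::HETNET_RELATIONS) {
    for (k in 1:2) {
      phi <- gat_attention(X, net, par, r, k)
      deg <- rowSums(net$relations[[r]])
      expect_equal(unname(rowSums(phi)[deg > 0]),
                   rep(1, sum(deg > 0)), tolerance = 1e-12)
      expect_true(all(rowSums(phi)[deg == 0] == 0))
    }
  }
  # single neighbour -> coefficient exactly 1
  star <- assemble_network(
    c("d1", "d2"), c("t1"),
    matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(c("d1", "d2"), c("d1", "d2"))),
    matrix(0L, 2, 1, dimnames = list(c("d1", "d2"), "t1")),
    matrix(0L, 1, 1, dimnames = list("t1", "t1")))
  phi <- gat_attention(matrix(rnorm(6), 3, 2), star, init_gat_params(2, 3, K = 1, seed = 1),
                       "drug_drug_interaction", 1)
  expect_equal(phi[1, 2], 1)
  expect_equal(phi[2, 1], 1)
})

test_that("attention logits match a scalar enumeration oracle", {
  # 3-node star under one relation with fixed small weights
  ids <- c("d1", "d2", "d3")
  ddi <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  ddi["d1", "d2"] <- ddi["d2", "d1"] <- 1L
  ddi["d1", "d3"] <- ddi["d3", "d1"] <- 1L
  net <- assemble_network(ids, "t1", ddi,
                          matrix(0L, 3, 1, dimnames = list(ids, "t1")),
                          matrix(0L, 1, 1, dimnames = list("t1", "t1")))
  set.seed(3)
  X <- matrix(rnorm(8), 4, 2)
  par <- init_gat_params(2, 2, K = 1, db = 2, seed = 3)
  phi <- gat_attention(X, net, par, "drug_drug_interaction", 1)
  # scalar oracle
  H <- X %*% par$W[[1]]
  a <- par$a[[1]]
  lrelu <- function(z) ifelse(z > 0, z, 0.2 * z)
  cr <- sum(a[5:6] * par$B[[1]][, 1])
  logit <- function(i, j) lrelu(sum(a[1:2] * H[i, ]) + sum(a[3:4] * H[j, ]) + cr)
  e12 <- exp(logit(1, 2)); e13 <- exp(logit(1, 3))
  expect_equal(phi[1, 2], e12 / (e12 + e13), tolerance = 1e-6)
  expect_equal(phi[1, 3], e13 / (e12 + e13), tolerance = 1e-6)
  expect_equal(phi[2, 1], 1, tolerance = 1e-12)
})

test_that("multi-head propagation averages heads and sums relations", {
  net <- tiny_hetnet(seed = 13)
  set.seed(13)
  X <- matrix(rnorm(9 * 3), 9, 3)
  # K = 1 reduces to single-head attention
  p1 <- init_gat_params(3, 4, K = 1, seed = 13)
  out1 <- gat_propagate(X, net, p1)
  manual <- NULL
  for (r in hetdti:::HETNET_RELATIONS) {
    phi <- gat_attention(X, net, p1, r, 1)
    H <- pmax(phi %*% (X %*% p1$W[[1]]), 0)
    manual <- if (is.null(manual)) H else manual + H
  }
  expect_equal(out1, manual, tolerance = 1e-10, ignore_attr = TRUE)
  # a node isolated under every relation maps to zero
  iso <- assemble_network(
    c("d1", "d2"), c("t1"),
    matrix(0L, 2, 2, dimnames = list(c("d1", "d2"), c("d1", "d2"))),
    matrix(c(0L, 1L), 2, 1, dimnames = list(c("d1", "d2"), "t1")),
    matrix(0L, 1, 1, dimnames = list("t1", "t1")))
  out_iso <- gat_propagate(matrix(rnorm(9), 3, 3), iso,
                           init_gat_params(3, 4, K = 2, seed = 2))
  expect_equal(unname(out_iso[1, ]), rep(0, 4))
})

test_that("node encoding fuses the first and third layer outputs", {
  net <- tiny_hetnet(seed = 21)
  set.seed(21)
  X0 <- matrix(rnorm(9 * 4), 9, 4)
  par <- init_encoder_params(4, d_hidden = 6, d = 5, K = 2, db = 2, seed = 21)
  enc <- encode_nodes(X0, net, par)
  expect_equal(dim(enc$X_D), c(4, 5))
  expect_equal(dim(enc$X_T), c(5, 5))
  expect_equal(enc$X,
               sweep(cbind(enc$X1, enc$X3) %*% par$fuse_W, 2, par$fuse_b, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # with zero third-layer weights the fusion depends only on X1
  par0 <- par
  for (r in hetdti:::HETNET_RELATIONS) par0$layers[[3]][[r]][] <- 0
  enc0 <- encode_nodes(X0, net, par0)
  expect_equal(enc0$X,
               sweep(cbind(enc0$X1, enc0$X3 * 0) %*% par$fuse_W, 2,
                     par$fuse_b, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # the alternative layer stack runs
  par2 <- init_encoder_params(4, 6, 5, K = 2, db = 2,
                              layer_order = c("gat", "gat", "gcn"), seed = 3)
  expect_equal(dim(encode_nodes(X0, net, par2)$X), c(9, 5))
})

test_that("permuting node order and permuting back leaves encodings unchanged", {
  net <- tiny_hetnet(seed = 31)
  set.seed(31)
  X0 <- matrix(rnorm(9 * 3), 9, 3)
  par <- init_encoder_params(3, 4, 4, K = 2, db = 2, seed = 31)
  enc <- encode_nodes(X0, net, par)
  perm <- sample(9)
  net_p <- net
  for (r in hetdti:::HETNET_RELATIONS) {
    net_p$relations[[r]] <- net$relations[[r]][perm, perm]
  }
  enc_p <- encode_nodes(X0[perm, , drop = FALSE], net_p, par)
  expect_equal(enc_p$X[order(perm), ], enc$X, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("binary cross-entropy reproduces the analytic values", {
  expect_equal(bce_loss(qlogis(c(0.5, 0.5)), c(1, 0)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(qlogis(c(0.9, 0.1)), c(1, 0)),
               -(log(0.9) + log(0.9)) / 2, tolerance = 1e-9)
  expect_lt(bce_loss(qlogis(c(1 - 1e-9, 1e-9)), c(1, 0)), 1e-5)
  # weighted form counts duplicated pairs
  expect_equal(bce_loss(qlogis(c(0.9, 0.1)), c(1, 0), weights = c(2, 0)),
               -log(0.9), tolerance = 1e-9)
})

test_that("joint training is seeded, monotone on easy data, frozen at lr 0", {
  b <- small_bundle(seed = 6L)
  cfg <- fast_config(seed = 2, epochs = 10L)
  f1 <- dti_fit(b, cfg)
  f2 <- dti_fit(b, cfg)
  expect_identical(f1$log, f2$log)                  # same seed, same curve
  expect_lt(utils::tail(f1$log$train, 1), f1$log$train[1])  # loss decreases
  # a broadly non-increasing trend: average late loss < average early loss
  expect_lt(mean(utils::tail(f1$log$train, 3)), mean(utils::head(f1$log$train, 3)))
  cfg0 <- fast_config(seed = 2, epochs = 3L)
  cfg0$lr <- 0
  f0 <- dti_fit(b, cfg0)
  expect_equal(sd(f0$log$train), 0, tolerance = 1e-12)  # parameters unchanged
})
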