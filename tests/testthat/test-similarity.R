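# Similarity scores: Jaccard over association neighbourhoods, MACCS /
# Tanimoto fingerprints, composition-based protein similarity, and the
# thresholded similarity-edge rule.

test_that("Jaccard similarity matches the neighbour-set oracle", {
  toys <- generate_worked_toys()
  S <- jaccard_network_similarity(toys$jac)
  expect_equal(S["D1", "D2"], 0.5)   # {a,b,c} vs {b,c,d}
  expect_equal(diag(S), c(D1 = 1, D2 = 1))
  # identical, disjoint and empty neighbour sets
  A <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  S2 <- jaccard_network_similarity(A)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], 0)
  expect_equal(S2[4, 4], 0)          # empty set scores 0, even with itself
  expect_error(jaccard_network_similarity(matrix(2, 2, 2)), "boolean")
  # vectorised result equals a brute-force double loop over neighbour sets
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rbinom(50 * 30, 1, 0.2), 50, 30)
    S <- jaccard_network_similarity(A)
    idx <- cbind(sample(50, 15, replace = TRUE), sample(50, 15, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      a <- which(A[i, ] == 1); b <- which(A[j, ] == 1)
      expected <- if (length(union(a, b)) == 0) 0 else
        length(intersect(a, b)) / length(union(a, b))
      expect_equal(S[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("MACCS fingerprints have 167 bits and match the reference keys", {
  fp <- maccs_fingerprint("CCO")
  expect_length(fp, 167)
  expect_true(all(fp %in% c(0L, 1L)))
  # on-bit key numbers frozen from an independent structural-key
  # implementation (0-based positions = key ids)
  expect_identical(which(fp == 1L) - 1L,
                   c(82L, 109L, 114L, 139L, 153L, 155L, 157L, 160L, 164L))
  expect_identical(which(maccs_fingerprint("c1ccccc1") == 1L) - 1L,
                   c(162L, 163L, 165L))
  expect_identical(
    which(maccs_fingerprint("CC(=O)Oc1ccccc1C(=O)O") == 1L) - 1L,
    c(89L, 113L, 123L, 126L, 127L, 136L, 139L, 140L, 143L, 144L, 146L,
      150L, 152L, 154L, 157L, 159L, 160L, 162L, 163L, 164L, 165L))
  # equivalent SMILES of one molecule give identical fingerprints
  expect_identical(maccs_fingerprint("OCC"), maccs_fingerprint("CCO"))
  expect_error(maccs_fingerprint("notasmiles[["), "unparseable|unbalanced")
})

test_that("Tanimoto coefficient matches the bit-count oracle", {
  toys <- generate_worked_toys()
  expect_equal(tanimoto(toys$fp$f1, toys$fp$f2), 1 / 3)  # {1,3} vs {2,3}
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
  for (seed in 1:20) {
    set.seed(seed)
    f1 <- rbinom(167, 1, 0.3); f2 <- rbinom(167, 1, 0.3)
    n11 <- sum(f1 & f2)
    expect_equal(tanimoto(f1, f2),
                 if (sum(f1) + sum(f2) - n11 == 0) 0 else
                   n11 / (sum(f1) + sum(f2) - n11), tolerance = 1e-12)
  }
})

test_that("protein sequence similarity follows the printed formula, clamped", {
  expect_equal(protein_sequence_similarity("MKVL", "MKVL"), 1)
  expect_equal(protein_sequence_similarity("AAAA", "AAAC"), 0.5)
  # completely different equal-length compositions clamp at 0
  expect_equal(protein_sequence_similarity("AAAA", "CCCC"), 0)
  expect_error(protein_sequence_similarity("", "AA"))
  # random instances vs the count-table oracle
  for (seed in 1:20) {
    set.seed(seed)
    p1 <- paste(sample(amino_acids(), sample(5:30, 1), TRUE), collapse = "")
    p2 <- paste(sample(amino_acids(), sample(5:30, 1), TRUE), collapse = "")
    cnt <- function(s) table(factor(strsplit(s, "")[[1]], levels = amino_acids()))
    E <- sum(abs(cnt(p1) - cnt(p2)))
    I <- abs(nchar(p1) - nchar(p2)) + 2 * E
    L <- (nchar(p1) + nchar(p2) - I) / (nchar(p1) + nchar(p2))
    expect_equal(protein_sequence_similarity(p1, p2), min(1, max(0, L)),
                 tolerance = 1e-12)
  }
  # matrix form is symmetric with unit diagonal
  S <- sequence_similarity_matrix(c(a = "MKVLAW", b = "MKVLAA", c = "CCCCCC"))
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
})

test_that("similarity edges obey the strict threshold and interaction veto", {
  S <- matrix(c(1, 0.9, 0.4,
                0.9, 1, 0.6,
                0.4, 0.6, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  class(S) <- c("similarity_matrix", class(S)); attr(S, "source") <- "test"
  none <- matrix(0, 3, 3)
  expect_equal(nrow(add_similarity_edges(list(S), 1.0, none)), 0)   # strict >
  e0 <- add_similarity_edges(list(S), 0, none)
  expect_equal(nrow(e0), 3)                                          # all pairs
  e5 <- add_similarity_edges(list(S), 0.5, none)
  expect_identical(sort(paste(e5$id_a, e5$id_b)), c("a b", "b c"))
  # an existing interaction vetoes the edge even at score 0.9
  inter <- none; inter[1, 2] <- inter[2, 1] <- 1
  ev <- add_similarity_edges(list(S), 0.5, inter)
  expect_identical(paste(ev$id_a, ev$id_b), "b c")
  # max over several sources decides, and dimension mismatch errors
  expect_error(add_similarity_edges(list(S, S[1:2, 1:2]), 0.5), "dimension")
})

test_that("drugs have four similarity sources and targets three", {
  b <- small_bundle(seed = 4L)
  expect_length(hetdti:::.drug_similarities(b), 4L)
  expect_length(hetdti:::.target_similarities(b), 3L)
  src_d <- vapply(hetdti:::.drug_similarities(b), attr, "", "source")
  expect_setequal(src_d, c("network-disease", "network-interaction",
                           "network-sideeffect", "fingerprint"))
  src_t <- vapply(hetdti:::.target_similarities(b), attr, "", "source")
  expect_setequal(src_t, c("network-disease", "network-interaction",
                           "sequence"))
  # all outputs symmetric and within [0, 1]
  for (S in c(hetdti:::.drug_similarities(b), hetdti:::.target_similarities(b))) {
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unclass(S), t(unclass(S)), ignore_attr = TRUE)
  }
})
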