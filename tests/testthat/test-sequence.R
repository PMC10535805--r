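# Tokenization, vocabularies and one-hot sequence embeddings.

test_that("protein k-mer tokenization yields the overlapping windows", {
  expect_identical(tokenize_protein("ABCDE", 3), c("ABC", "BCD", "CDE"))
  expect_identical(tokenize_protein("MKVL", 1), c("M", "K", "V", "L"))
  expect_error(tokenize_protein("MK", 3, id = "p1"), "p1.*too short|too short")
  # window count law over random lengths
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(3:60, 1)
    k <- sample(seq_len(n), 1)
    s <- paste(sample(amino_acids(), n, replace = TRUE), collapse = "")
    expect_length(tokenize_protein(s, k), n - k + 1)
  }
})

test_that("k-mer vocabulary sizes and determinism", {
  expect_equal(build_kmer_vocabulary(k = 1)$size, 20)
  v3 <- build_kmer_vocabulary(k = 3)
  expect_equal(v3$size, 8000)
  expect_equal(unname(v3$index[["AAA"]]), 0L)
  expect_identical(v3$index, build_kmer_vocabulary(k = 3)$index)
  expect_equal(build_kmer_vocabulary("AAA", k = 3, mode = "corpus")$size, 1)
  expect_error(build_kmer_vocabulary(character(0), k = 2, mode = "corpus"))
  expect_equal(build_kmer_vocabulary(k = 2, unk = TRUE)$size, 401)
})

test_that("SMILES tokenization is lossless and handles multi-char tokens", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_identical(tokenize_smiles("C[NH3+]Br"), c("C", "[NH3+]", "Br"))
  expect_error(tokenize_smiles("C[NH"), "unbalanced")
  set.seed(2)
  toys <- unlist(hetdti:::.smiles_templates())
  for (s in sample(toys, 30)) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
  # ring-closure digits are individual tokens
  tk <- tokenize_smiles("C1=CC=CC=C1")
  expect_length(tk, 11)
  expect_identical(paste(tk, collapse = ""), "C1=CC=CC=C1")
})

test_that("one-hot embeddings satisfy the masking and truncation contract", {
  v <- build_kmer_vocabulary(k = 3)
  e <- encode_protein("ACDEG", v, 10)
  M <- as.matrix(e)
  expect_equal(dim(M), c(8000, 10))
  expect_equal(colSums(M), c(1, 1, 1, rep(0, 7)))
  expect_identical(embedding_mask(e), c(rep(TRUE, 3), rep(FALSE, 7)))
  # truncation from the right
  et <- encode_protein("ACDEG", v, 2)
  expect_equal(et$n_valid, 2L)
  expect_identical(decode_embedding(et), decode_embedding(e)[1:2])
  # drug embeddings use the 61-token vocabulary
  d <- encode_drug("CCOc1ccccc1", L_D = 16)
  expect_equal(d$C, 61L)
  expect_true(all(colSums(as.matrix(d))[seq_len(d$n_valid)] == 1))
  # round-trip through encode/decode recovers the token indices
  sv <- default_smiles_vocabulary()
  idx <- unname(sv$index[tokenize_smiles("CCOc1ccccc1")])
  expect_identical(decode_embedding(d), as.integer(idx))
})

test_that("unknown-token policies behave as configured", {
  v <- build_kmer_vocabulary(k = 1)
  expect_error(encode_protein("ACX", v, 5, policy = "error", id = "p9"), "p9")
  vu <- build_kmer_vocabulary(k = 1, unk = TRUE)
  eu <- encode_protein("ACX", vu, 5, policy = "unk")
  expect_equal(decode_embedding(eu)[3], vu$unk_index)
  ed <- encode_protein("ACX", v, 5, policy = "drop")
  expect_equal(ed$n_valid, 2L)
})

test_that("identical inputs give bit-identical embeddings", {
  v <- build_kmer_vocabulary(k = 2)
  a <- as.matrix(encode_protein("MKVLAW", v, 8))
  b <- as.matrix(encode_protein("MKVLAW", v, 8))
  expect_identical(a, b)
})

test_that("FASTA and SMILES TSV readers round-trip", {
  tmp <- withr::local_tempdir()
  seqinr::write.fasta(list("MKVLAW", "ACDEFG"), c("p1 desc here", "p2"),
                      file.path(tmp, "x.fasta"), as.string = TRUE)
  ps <- read_protein_fasta(file.path(tmp, "x.fasta"))
  expect_identical(ps, c(p1 = "MKVLAW", p2 = "ACDEFG"))
  write.table(data.frame(drug_id = c("d1", "d2"), smiles = c("CCO", "CCN")),
              file.path(tmp, "d.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_identical(read_smiles_tsv(file.path(tmp, "d.tsv")),
                   c(d1 = "CCO", d2 = "CCN"))
  v <- make_token_vocabulary(c("C", "O"))
  write_vocabulary_json(v, file.path(tmp, "v.json"))
  back <- jsonlite::read_json(file.path(tmp, "v.json"), simplifyVector = TRUE)
  expect_equal(unlist(back), c(C = 0, O = 1))
})
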