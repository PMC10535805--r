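# Sequence tokenization and one-hot encoding for proteins (overlapping
# k-mers over the 20-letter amino-acid alphabet) and drug SMILES strings
# (per-token), producing the channel-by-length original embeddings consumed
# by the convolutional feature extractor.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in lexicographic order.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.NONCANONICAL <- c("B", "J", "O", "U", "X", "Z")
.UNK_TOKEN <- "<unk>"

#' Tokenize a protein sequence into overlapping k-mers
#'
#' Slides a window of width `k` one residue at a time, producing the
#' `n - k + 1` overlapping windows in sequence order (e.g. a 5-residue
#' sequence with `k = 3` yields 3 windows).
#'
#' @param residues Character scalar, the residue string.
#' @param k Window width (positive integer), default 3.
#' @param id Optional sequence id used in error messages.
#' @return Character vector of k-mer tokens.
#' @export
tokenize_protein <- function(residues, k = 3L, id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L, k >= 1L)
  n <- nchar(residues)
  if (n < k) {
    stop(sprintf("sequence %stoo short: length %d < k = %d",
                 if (is.null(id)) "" else paste0("'", id, "' "), n, k))
  }
  substring(residues, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Build a k-mer vocabulary
#'
#' In `"full"` mode the vocabulary is the complete 20^k canonical k-mer
#' space (corpus-independent, lexicographically ordered). In `"corpus"`
#' mode it is restricted to the k-mers observed in `sequences`. Setting
#' `unk = TRUE` appends a single unknown-token channel so windows
#' containing non-canonical residues (B, J, O, U, X, Z) can be encoded.
#'
#' @param sequences Character vector of residue strings (required for
#'   `"corpus"` mode; ignored in `"full"` mode).
#' @param k Window width.
#' @param mode `"full"` or `"corpus"`.
#' @param unk Append an unknown-token channel?
#' @return Object of class `kmer_vocab`: list with `k`, `mode`, `index`
#'   (named integer map token -> 0-based index), `size`, `unk_index`.
#' @export
build_kmer_vocabulary <- function(sequences = NULL, k = 3L,
                                  mode = c("full", "corpus"), unk = FALSE) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L)
  if (mode == "full") {
    toks <- amino_acids()
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        toks <- as.vector(outer(toks, amino_acids(), paste0))
      }
    }
    toks <- sort(toks)
  } else {
    if (is.null(sequences) || length(sequences) == 0L) {
      stop("corpus mode requires a non-empty sequence collection")
    }
    toks <- sort(unique(unlist(lapply(sequences, tokenize_protein, k = k))))
  }
  if (unk) toks <- c(toks, .UNK_TOKEN)
  idx <- seq_along(toks) - 1L
  names(idx) <- toks
  structure(list(k = as.integer(k), mode = mode, index = idx,
                 size = length(toks),
                 unk_index = if (unk) idx[[.UNK_TOKEN]] else NA_integer_),
            class = "kmer_vocab")
}

#' Default SMILES token vocabulary (61 tokens)
#'
#' A frozen list covering the organic-subset atoms, aromatic atoms, ring
#' digits, bond/branch symbols and common bracket atoms, plus an unknown
#' token, 61 tokens in total.
#'
#' @return Object of class `token_vocab` (named 0-based integer map).
#' @export
default_smiles_vocabulary <- function() {
  toks <- c(
    "C", "N", "O", "S", "P", "F", "I", "B", "Cl", "Br",
    "c", "n", "o", "s", "p",
    as.character(0:9),
    "-", "=", "#", ":", "/", "\\", ".", "(", ")",
    "[C@H]", "[C@@H]", "[C@]", "[C@@]", "[CH]", "[CH2]",
    "[N+]", "[N-]", "[NH+]", "[NH2+]", "[NH3+]", "[nH]", "[n+]",
    "[O-]", "[OH]", "[S+]", "[s+]", "[Se]", "[se]", "[Si]",
    "[P+]", "[B-]", "[Na+]", "[Cl-]", "[Br-]", "[I-]",
    .UNK_TOKEN)
  make_token_vocabulary(toks)
}

#' Build a SMILES token vocabulary
#'
#' @param tokens Character vector of distinct tokens (order defines index).
#' @return Object of class `token_vocab`.
#' @export
make_token_vocabulary <- function(tokens) {
  stopifnot(!anyDuplicated(tokens))
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  structure(list(index = idx, size = length(tokens),
                 unk_index = if (.UNK_TOKEN %in% tokens) idx[[.UNK_TOKEN]]
                             else NA_integer_),
            class = "token_vocab")
}

#' Build a SMILES vocabulary from a corpus
#'
#' Tokens observed in `smiles` (sorted), padded with an unknown token.
#' @param smiles Character vector of SMILES strings.
#' @return Object of class `token_vocab`.
#' @export
build_smiles_vocabulary <- function(smiles) {
  stopifnot(length(smiles) > 0L)
  toks <- sort(unique(unlist(lapply(smiles, tokenize_smiles))))
  make_token_vocabulary(c(toks, .UNK_TOKEN))
}

#' Tokenize a SMILES string
#'
#' Lossless tokenization: bracket atoms `[...]` are single tokens, the
#' two-letter halogens Cl and Br are single tokens, two-digit ring
#' closures `%nn` are single tokens, and every other character (atom,
#' bond, branch, ring digit) is one token. Concatenating the tokens
#' reproduces the input exactly.
#'
#' @param smiles Character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  n_open <- lengths(regmatches(smiles, gregexpr("\\[", smiles)))
  n_close <- lengths(regmatches(smiles, gregexpr("\\]", smiles)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced brackets in SMILES '%s'", smiles))
  }
  pat <- "\\[[^][]*\\]|Cl|Br|%[0-9]{2}|."
  toks <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stop(sprintf("tokenization failed to round-trip SMILES '%s'", smiles))
  }
  toks
}

# map tokens to 0-based vocabulary indices under an unknown-token policy
.tokens_to_index <- function(tokens, vocab, policy = c("unk", "error", "drop"),
                             id = NULL) {
  policy <- match.arg(policy)
  idx <- unname(vocab$index[tokens])
  bad <- is.na(idx)
  if (any(bad)) {
    if (policy == "error") {
      stop(sprintf("unknown token(s) %s in sequence %s",
                   paste(unique(tokens[bad]), collapse = ", "),
                   if (is.null(id)) "" else id))
    } else if (policy == "drop") {
      idx <- idx[!bad]
    } else {
      if (is.na(vocab$unk_index)) {
        stop("policy 'unk' requires a vocabulary with an unknown token")
      }
      idx[bad] <- vocab$unk_index
    }
  }
  as.integer(idx)
}

# shared constructor for one-hot sequence embeddings; tokens are kept as
# 0-based channel indices (a sparse representation of the one-hot matrix)
.new_embedding <- function(id, token_idx, C, L, kind) {
  stopifnot(L >= 1L)
  n_valid <- min(length(token_idx), L)
  structure(list(id = id, kind = kind,
                 token_idx = token_idx[seq_len(n_valid)],
                 C = as.integer(C), L = as.integer(L),
                 n_valid = as.integer(n_valid)),
            class = "seq_embedding")
}

#' Encode a protein sequence as a one-hot k-mer embedding
#'
#' Produces a channel-by-length one-hot matrix: channel count equals the
#' vocabulary size, columns `1..min(n - k + 1, L_T)` are one-hot (one per
#' k-mer window), remaining columns are zero-masked padding. Sequences
#' with more windows than `L_T` are truncated from the right.
#'
#' @param residues Residue string.
#' @param vocab A `kmer_vocab`.
#' @param L_T Maximum (padded) length, >= 1.
#' @param policy Unknown-token policy: `"unk"`, `"error"` or `"drop"`.
#' @param id Optional sequence id.
#' @return Object of class `seq_embedding` (sparse one-hot; see
#'   [as.matrix.seq_embedding()]).
#' @export
encode_protein <- function(residues, vocab, L_T, policy = "unk", id = NULL) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  toks <- tokenize_protein(residues, vocab$k, id = id)
  idx <- .tokens_to_index(toks, vocab, policy, id = id)
  .new_embedding(id, idx, vocab$size, L_T, "protein")
}

#' Encode a drug SMILES string as a one-hot token embedding
#'
#' @param smiles SMILES string.
#' @param vocab A `token_vocab` (default: the frozen 61-token vocabulary).
#' @param L_D Maximum (padded) length, >= 1.
#' @inheritParams encode_protein
#' @return Object of class `seq_embedding`.
#' @export
encode_drug <- function(smiles, vocab = default_smiles_vocabulary(), L_D,
                        policy = "unk", id = NULL) {
  stopifnot(inherits(vocab, "token_vocab"))
  toks <- tokenize_smiles(smiles)
  idx <- .tokens_to_index(toks, vocab, policy, id = id)
  .new_embedding(id, idx, vocab$size, L_D, "drug")
}

#' Materialize a sequence embedding as a dense channel-by-length matrix
#'
#' @param x A `seq_embedding`.
#' @param ... Unused.
#' @return Numeric matrix `C x L`; unmasked columns are one-hot, padded
#'   columns all-zero.
#' @export
as.matrix.seq_embedding <- function(x, ...) {
  M <- matrix(0, x$C, x$L)
  if (x$n_valid > 0L) {
    M[cbind(x$token_idx + 1L, seq_len(x$n_valid))] <- 1
  }
  M
}

#' Column mask of a sequence embedding
#'
#' @param x A `seq_embedding`.
#' @return Logical vector of length `L`, `TRUE` for unmasked (data)
#'   columns.
#' @export
embedding_mask <- function(x) {
  stopifnot(inherits(x, "seq_embedding"))
  seq_len(x$L) <= x$n_valid
}

#' Recover the (possibly truncated) token indices from an embedding
#'
#' @param x A `seq_embedding`.
#' @return Integer vector of 0-based channel indices.
#' @export
decode_embedding <- function(x) {
  stopifnot(inherits(x, "seq_embedding"))
  x$token_idx
}

#' Default padded length: 95th-percentile corpus length rounded up to a
#' multiple of 8
#'
#' @param lengths Integer vector of token-sequence lengths.
#' @return Integer padded length.
#' @export
default_padded_length <- function(lengths) {
  q <- stats::quantile(lengths, 0.95, type = 7, names = FALSE)
  max(8L, as.integer(ceiling(q / 8) * 8))
}

#' Read protein sequences from a FASTA file
#'
#' The id of each sequence is the first whitespace-delimited word of its
#' header line.
#'
#' @param path FASTA file path.
#' @return Named character vector of residue strings (uppercased).
#' @export
read_protein_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- toupper(vapply(recs, `[[`, "", 1L))
  names(out) <- vapply(strsplit(names(recs), "\\s+"), `[[`, "", 1L)
  out
}

#' Read drug SMILES from a two-column TSV (id, smiles)
#'
#' @param path TSV file path with header `drug_id<TAB>smiles`.
#' @return Named character vector of SMILES strings.
#' @export
read_smiles_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  out <- df[[2L]]
  names(out) <- as.character(df[[1L]])
  out
}

#' Serialize a vocabulary to JSON (token -> index map)
#'
#' @param vocab A `kmer_vocab` or `token_vocab`.
#' @param path Output path.
#' @export
write_vocabulary_json <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$index), path, auto_unbox = TRUE)
  invisible(path)
}
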