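# Multi-source similarity scores used to augment the drug-protein network
# with similarity edges: Jaccard similarity over association-network
# neighbour sets, Tanimoto similarity of MACCS structural-key
# fingerprints, and a length/composition-based protein sequence
# similarity. A pair receives a similarity edge when any of its scores
# exceeds a threshold and the pair has no recorded interaction.

#' Jaccard similarity between rows of a boolean association matrix
#'
#' For entities i and j with neighbour sets taken from the rows of `A`,
#' `S[i, j] = N11 / (N01 + N10 + N11)` where N11 counts shared
#' neighbours and N01/N10 count neighbours exclusive to either entity.
#' Two empty neighbour sets score 0 (no evidence of similarity).
#'
#' @param A Boolean (0/1) matrix, rows = entities, columns = the
#'   associated entities (diseases, side effects, interaction partners).
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal for
#'   entities with at least one neighbour; class `similarity_matrix`
#'   attributes carry the source tag.
#' @param source Source tag stored on the result.
#' @export
jaccard_network_similarity <- function(A, source = "network") {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("association matrix must be boolean (0/1)")
  inter <- tcrossprod(A)              # N11
  deg <- rowSums(A)
  uni <- outer(deg, deg, "+") - inter # N01 + N10 + N11
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(rownames(A), rownames(A))
  structure(S, source = source, class = c("similarity_matrix", class(S)))
}

#' MACCS structural-key fingerprint of a drug
#'
#' Computes the public 166-key structural-key fingerprint (OpenBabel
#' backend) and returns it in the standard 167-bit layout: bit 0 is
#' reserved and key `i` sits at 0-based position `i`.
#'
#' @param smiles SMILES string.
#' @param backend Function `smiles -> 0/1 vector of length 166` (key i at
#'   position i); the default uses ChemmineOB/OpenBabel. Pluggable for
#'   alternative structural-key implementations.
#' @return Integer 0/1 vector of length 167.
#' @export
maccs_fingerprint <- function(smiles, backend = maccs_backend_openbabel) {
  bits166 <- backend(smiles)
  if (length(bits166) != 166L) stop("fingerprint backend must return 166 keys")
  as.integer(c(0L, bits166))
}

#' OpenBabel MACCS backend
#' @param smiles SMILES string.
#' @return 0/1 vector of length 166 (key i at position i).
#' @export
maccs_backend_openbabel <- function(smiles) {
  fp <- tryCatch(
    ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", smiles,
                                                      identity), "MACCS"),
    error = function(e) stop(sprintf("unparseable SMILES '%s': %s",
                                     smiles, conditionMessage(e))))
  as.integer(fp[seq_len(166L)] != 0)
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `T = N11 / (N01 + N10 - N11)` with N11 the shared on-bits and N01/N10
#' the total on-bits of each fingerprint; two all-zero fingerprints
#' score 0.
#'
#' @param f1,f2 Equal-length 0/1 vectors.
#' @return Numeric scalar in `[0, 1]`.
#' @export
tanimoto <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("fingerprint length mismatch")
  n11 <- sum(f1 == 1 & f2 == 1)
  n01 <- sum(f1 == 1)
  n10 <- sum(f2 == 1)
  den <- n01 + n10 - n11
  if (den == 0) 0 else n11 / den
}

#' Fingerprint-based drug-drug similarity matrix
#'
#' @param smiles Named character vector of SMILES.
#' @param backend Passed to [maccs_fingerprint()].
#' @return `similarity_matrix` (source `"fingerprint"`). Drugs whose
#'   SMILES cannot be parsed are excluded (scored 0 against everything,
#'   with a warning).
#' @export
fingerprint_similarity <- function(smiles, backend = maccs_backend_openbabel) {
  n <- length(smiles)
  fps <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    fps[[i]] <- tryCatch(maccs_fingerprint(smiles[[i]], backend),
                         error = function(e) {
                           warning(sprintf("drug %s excluded: %s",
                                           names(smiles)[i],
                                           conditionMessage(e)))
                           ok[i] <<- FALSE
                           NULL
                         })
  }
  S <- matrix(0, n, n, dimnames = list(names(smiles), names(smiles)))
  F <- do.call(rbind, lapply(fps[ok], as.numeric))
  if (!is.null(F) && nrow(F) > 0L) {
    inter <- tcrossprod(F)
    on <- rowSums(F)
    den <- outer(on, on, "+") - inter
    S[ok, ok] <- ifelse(den > 0, inter / den, 0)
  }
  structure(S, source = "fingerprint", class = c("similarity_matrix", class(S)))
}

#' Length/composition protein sequence similarity
#'
#' With `S1`, `S2` the two sequence lengths and `E` the total absolute
#' difference of per-residue-type counts, the dissimilarity is
#' `I = |S1 - S2| + 2 E` and the similarity `L = (S1 + S2 - I) /
#' (S1 + S2)`, clamped to `[0, 1]`.
#'
#' @param p1,p2 Residue strings (non-empty).
#' @return Numeric scalar in `[0, 1]`.
#' @export
protein_sequence_similarity <- function(p1, p2) {
  stopifnot(nzchar(p1), nzchar(p2))
  s1 <- nchar(p1); s2 <- nchar(p2)
  r1 <- strsplit(p1, "")[[1]]
  r2 <- strsplit(p2, "")[[1]]
  alph <- union(r1, r2)
  E <- sum(abs(table(factor(r1, levels = alph)) -
               table(factor(r2, levels = alph))))
  I <- abs(s1 - s2) + 2 * E
  min(1, max(0, (s1 + s2 - I) / (s1 + s2)))
}

#' Sequence-similarity matrix over a set of proteins
#'
#' @param sequences Named character vector of residue strings.
#' @return `similarity_matrix` (source `"sequence"`).
#' @export
sequence_similarity_matrix <- function(sequences) {
  n <- length(sequences)
  # vectorised composition table: residue counts per sequence
  res <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  alph <- sort(unique(unlist(res)))
  Cnt <- t(vapply(res, function(r) as.numeric(table(factor(r, levels = alph))),
                  numeric(length(alph))))
  len <- nchar(sequences)
  S <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n)) {
    E <- colSums(abs(t(Cnt) - Cnt[i, ]))
    I <- abs(len - len[i]) + 2 * E
    S[i, ] <- pmin(1, pmax(0, (len + len[i] - I) / (len + len[i])))
  }
  structure(S, source = "sequence", class = c("similarity_matrix", class(S)))
}

#' Thresholded similarity edges
#'
#' A pair (i, j), i < j, receives a similarity edge iff the maximum of
#' its scores across all sources is strictly greater than `threshold` and
#' the pair has no existing interaction.
#'
#' @param scores List of `similarity_matrix` objects of identical
#'   dimension (same entity kind).
#' @param threshold Numeric in `[0, 1]`.
#' @param existing Boolean interaction matrix of the same dimension (the
#'   same-kind interaction relation); pairs with `existing[i, j] == 1`
#'   are excluded.
#' @return Data frame `id_a`, `id_b`, `score`, `source` (one row per
#'   undirected edge, i < j).
#' @export
add_similarity_edges <- function(scores, threshold, existing = NULL) {
  stopifnot(length(scores) >= 1L, threshold >= 0, threshold <= 1)
  n <- nrow(scores[[1L]])
  for (S in scores) {
    if (!all(dim(S) == c(n, n))) stop("similarity matrices differ in dimension")
  }
  if (is.null(existing)) existing <- matrix(0, n, n)
  if (!all(dim(existing) == c(n, n))) stop("interaction matrix dimension mismatch")
  ids <- rownames(scores[[1L]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  best <- matrix(-Inf, n, n)
  src <- matrix(NA_character_, n, n)
  for (S in scores) {
    tag <- attr(S, "source")
    upd <- S > best
    best[upd] <- S[upd]
    src[upd] <- if (is.null(tag)) "unknown" else tag
  }
  keep <- which(upper.tri(best) & best > threshold & existing == 0,
                arr.ind = TRUE)
  data.frame(id_a = ids[keep[, 1L]], id_b = ids[keep[, 2L]],
             score = best[keep], source = src[keep],
             stringsAsFactors = FALSE)
}

#' Write similarity edges as TSV
#' @param edges Data frame from [add_similarity_edges()].
#' @param path Output path.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
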