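# Assembly and validation of the typed drug-protein network
# G = (V, E, R). Nodes are drugs and proteins only (drugs first, then
# proteins, each lexicographic by id); R holds five undirected relations:
# drug-drug interaction, drug-drug similarity, drug-protein interaction,
# protein-protein interaction, protein-protein similarity. Diseases and
# side effects enter only through the similarity computation, never as
# nodes.

HETNET_RELATIONS <- c("drug_drug_interaction", "drug_drug_similarity",
                      "drug_protein_interaction", "protein_protein_interaction",
                      "protein_protein_similarity")

#' Load a boolean association matrix
#'
#' Accepts either a two-column TSV edge list (`row_id<TAB>col_id`, with
#' header) or a dense 0/1 matrix TSV whose first column holds row ids and
#' whose header holds column ids. Duplicate edges are collapsed with a
#' warning; non-binary values are rejected.
#'
#' @param path TSV path.
#' @param row_ids,col_ids Optional reference id vectors; unknown ids then
#'   raise an error, and the result is aligned to these ids.
#' @param symmetric Mirror (i, j) to (j, i) (same-kind relations).
#' @return 0/1 integer matrix with dimnames.
#' @export
load_association <- function(path, row_ids = NULL, col_ids = NULL,
                             symmetric = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) == 2L && !all(vapply(df, is.numeric, TRUE))) {
    a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
    if (anyDuplicated(paste(a, b, sep = "\r"))) {
      warning("duplicate edges collapsed")
      keep <- !duplicated(paste(a, b, sep = "\r"))
      a <- a[keep]; b <- b[keep]
    }
    if (is.null(row_ids)) row_ids <- sort(unique(a))
    if (is.null(col_ids)) col_ids <- sort(unique(b))
    bad <- setdiff(c(if (!is.null(row_ids)) a, if (!is.null(col_ids)) b),
                   c(row_ids, col_ids))
    if (!all(a %in% row_ids) || !all(b %in% col_ids)) {
      stop(sprintf("unknown ids in %s: %s", path,
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
    M <- matrix(0L, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
    M[cbind(match(a, row_ids), match(b, col_ids))] <- 1L
  } else {
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- as.character(df[[1L]])
    storage.mode(M) <- "numeric"
    if (!all(M %in% c(0, 1))) stop(sprintf("non-binary values in %s", path))
    storage.mode(M) <- "integer"
    if (!is.null(row_ids)) {
      if (!all(rownames(M) %in% row_ids)) stop("unknown row ids")
      M <- M[match(row_ids, rownames(M)), , drop = FALSE]
    }
    if (!is.null(col_ids)) {
      if (!all(colnames(M) %in% col_ids)) stop("unknown column ids")
      M <- M[, match(col_ids, colnames(M)), drop = FALSE]
    }
  }
  if (symmetric) {
    M <- pmax(M, t(M))
  }
  M
}

#' Assemble the heterogeneous network
#'
#' @param drug_ids,protein_ids Node id vectors (disjoint; ordering is
#'   normalised to lexicographic).
#' @param ddi Drug-drug interaction 0/1 matrix (drugs x drugs).
#' @param dpi Drug-protein interaction 0/1 matrix (drugs x proteins).
#' @param ppi Protein-protein interaction 0/1 matrix.
#' @param drug_sim_edges,protein_sim_edges Similarity edge data frames
#'   from [add_similarity_edges()] (may be empty or NULL).
#' @return Object of class `hetnet`: node ids, node kinds, and one
#'   symmetric 0/1 adjacency over all nodes per relation (no stored
#'   self-loops).
#' @export
assemble_network <- function(drug_ids, protein_ids, ddi, dpi, ppi,
                             drug_sim_edges = NULL, protein_sim_edges = NULL) {
  drug_ids <- sort(as.character(drug_ids))
  protein_ids <- sort(as.character(protein_ids))
  if (length(intersect(drug_ids, protein_ids)) > 0L) {
    stop("drug and protein id sets must be disjoint")
  }
  ids <- c(drug_ids, protein_ids)
  n <- length(ids)
  kind <- c(rep("drug", length(drug_ids)), rep("protein", length(protein_ids)))
  di <- seq_along(drug_ids)
  pi_ <- length(drug_ids) + seq_along(protein_ids)

  blank <- function() matrix(0L, n, n, dimnames = list(ids, ids))
  rel <- setNames(replicate(5, blank(), simplify = FALSE), HETNET_RELATIONS)

  put_same <- function(R, M, idx, src_ids) {
    M <- M[src_ids, src_ids, drop = FALSE]
    R[idx, idx] <- pmax(M, t(M))
    R
  }
  rel$drug_drug_interaction <-
    put_same(rel$drug_drug_interaction, ddi, di, drug_ids)
  rel$protein_protein_interaction <-
    put_same(rel$protein_protein_interaction, ppi, pi_, protein_ids)
  M <- dpi[drug_ids, protein_ids, drop = FALSE]
  rel$drug_protein_interaction[di, pi_] <- M
  rel$drug_protein_interaction[pi_, di] <- t(M)

  put_edges <- function(R, edges, inter, label) {
    if (is.null(edges) || nrow(edges) == 0L) return(R)
    ia <- match(edges$id_a, ids); ib <- match(edges$id_b, ids)
    if (anyNA(ia) || anyNA(ib)) stop("similarity edge ids outside node set")
    if (any(inter[cbind(ia, ib)] == 1L)) {
      stop(sprintf("%s similarity edge coincides with an interaction", label))
    }
    R[cbind(ia, ib)] <- 1L
    R[cbind(ib, ia)] <- 1L
    R
  }
  rel$drug_drug_similarity <- put_edges(rel$drug_drug_similarity,
                                        drug_sim_edges,
                                        rel$drug_drug_interaction, "drug")
  rel$protein_protein_similarity <- put_edges(rel$protein_protein_similarity,
                                              protein_sim_edges,
                                              rel$protein_protein_interaction,
                                              "protein")
  for (r in HETNET_RELATIONS) diag(rel[[r]]) <- 0L

  structure(list(ids = ids, kind = kind,
                 drug_ids = drug_ids, protein_ids = protein_ids,
                 relations = rel),
            class = "hetnet")
}

#' Per-relation degree matrix
#'
#' Diagonal matrix of row sums of the self-loop-augmented adjacency
#' `I + S_r` (default) or of `S_r` itself. With self-loops the diagonal
#' is strictly positive, so the symmetric normalisation
#' `A_r^{-1/2} (I + S_r) A_r^{-1/2}` is always defined.
#'
#' @param S_r Square 0/1 adjacency.
#' @param with_self_loops Include the identity (default TRUE).
#' @return Diagonal numeric matrix.
#' @export
degree_matrix <- function(S_r, with_self_loops = TRUE) {
  stopifnot(nrow(S_r) == ncol(S_r))
  St <- if (with_self_loops) S_r + diag(nrow(S_r)) else S_r
  diag(rowSums(St), nrow(S_r))
}

# normalised propagation operator A^{-1/2} (I + S) A^{-1/2}
normalized_adjacency <- function(S_r) {
  St <- S_r + diag(nrow(S_r))
  dinv <- 1 / sqrt(rowSums(St))
  St * outer(dinv, dinv)
}

#' Audit the symmetry and typing invariants of a network
#' @param net A `hetnet`.
#' @return TRUE invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  di <- which(net$kind == "drug"); pi_ <- which(net$kind == "protein")
  for (r in HETNET_RELATIONS) {
    S <- net$relations[[r]]
    if (!isTRUE(all.equal(S, t(S)))) stop(sprintf("%s not symmetric", r))
    if (any(diag(S) != 0)) stop(sprintf("%s stores self-loops", r))
  }
  for (r in c("drug_drug_interaction", "drug_drug_similarity")) {
    if (any(net$relations[[r]][pi_, ] != 0)) stop(sprintf("%s touches proteins", r))
  }
  for (r in c("protein_protein_interaction", "protein_protein_similarity")) {
    if (any(net$relations[[r]][di, ] != 0)) stop(sprintf("%s touches drugs", r))
  }
  if (any(net$relations$drug_protein_interaction[di, di] != 0) ||
      any(net$relations$drug_protein_interaction[pi_, pi_] != 0)) {
    stop("drug_protein_interaction has same-kind edges")
  }
  invisible(TRUE)
}

#' Save a network as per-relation TSV edge lists plus a JSON manifest
#'
#' @param net A `hetnet`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in HETNET_RELATIONS) {
    S <- net$relations[[r]]
    idx <- which(upper.tri(S) & S == 1L, arr.ind = TRUE)
    utils::write.table(
      data.frame(id_a = net$ids[idx[, 1L]], id_b = net$ids[idx[, 2L]]),
      file.path(dir, paste0(r, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(n_drugs = length(net$drug_ids),
                   n_proteins = length(net$protein_ids),
                   drug_ids = net$drug_ids, protein_ids = net$protein_ids,
                   relations = as.list(setNames(
                     paste0(HETNET_RELATIONS, ".tsv"), HETNET_RELATIONS)))
  jsonlite::write_json(manifest, file.path(dir, "network.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a network saved by [save_network()]
#' @param dir Directory containing `network.json` and relation TSVs.
#' @return A `hetnet`.
#' @export
load_network <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "network.json"),
                                  simplifyVector = TRUE)
  ids <- c(manifest$drug_ids, manifest$protein_ids)
  read_rel <- function(f) {
    df <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                            colClasses = "character")
    S <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(df) > 0L) {
      ia <- match(df$id_a, ids); ib <- match(df$id_b, ids)
      S[cbind(ia, ib)] <- 1L
      S[cbind(ib, ia)] <- 1L
    }
    S
  }
  rel <- lapply(manifest$relations, read_rel)
  structure(list(ids = ids,
                 kind = c(rep("drug", manifest$n_drugs),
                          rep("protein", manifest$n_proteins)),
                 drug_ids = manifest$drug_ids,
                 protein_ids = manifest$protein_ids,
                 relations = rel[HETNET_RELATIONS]),
            class = "hetnet")
}
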