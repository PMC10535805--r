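# Seeded generator of complete synthetic input bundles: drug SMILES,
# protein sequences, and the six boolean association networks, with
# planted community structure so that every similarity source is
# informative and the end-to-end pipeline has a recoverable signal.
# Drugs/targets/diseases/side effects are assigned to latent
# communities; interaction edges are Bernoulli(p_in) within a community
# and Bernoulli(p_out) across; disease and side-effect association
# profiles are community-correlated; SMILES come from family-structured
# valid templates and protein sequences have community-biased residue
# composition.

#' Synthetic bundle configuration
#'
#' Defaults are desk-scale: 60 drugs, 90 targets, 150 diseases, 120 side
#' effects, 3 communities, within-community interaction probability 0.25
#' against a 0.02 background, association-profile probabilities 0.15 /
#' 0.01, protein lengths 40-100 residues.
#'
#' @param n_drugs,n_targets,n_diseases,n_side_effects Entity counts.
#' @param n_communities Latent community count.
#' @param p_in,p_out Interaction edge probabilities (within / across
#'   communities) for the drug-target, drug-drug and target-target
#'   networks; requires `0 <= p_out <= p_in <= 1`.
#' @param q_in,q_out Association probabilities (within / across) for the
#'   disease and side-effect profiles.
#' @param protein_length Integer range (min, max) of residue counts.
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 60L, n_targets = 90L,
                             n_diseases = 150L, n_side_effects = 120L,
                             n_communities = 3L,
                             p_in = 0.25, p_out = 0.02,
                             q_in = 0.15, q_out = 0.01,
                             protein_length = c(40L, 100L),
                             seed = 1L) {
  stopifnot(p_out <= p_in, p_in <= 1, p_out >= 0,
            n_drugs >= 1L, n_targets >= 1L, n_communities >= 1L,
            protein_length[1L] >= 10L)
  structure(as.list(environment()), class = "synthetic_config")
}

# family-structured SMILES template library; each template is a valid
# SMILES with one {R} substitution point and at least 10 tokens once
# substituted
.smiles_templates <- function() {
  subs <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br",
            "C(C)C", "CO", "C#N", "C(=O)C", "C(=O)O", "CCO")
  fams <- list(
    # aromatic carbocycles
    c("Cc1ccc({R})cc1C", "CCc1ccccc1{R}", "Cc1cccc({R})c1O",
      "OCc1ccc({R})cc1", "CC(C)c1ccc({R})cc1", "Cc1ccc(C{R})cc1",
      "NCc1ccccc1{R}", "CC(=O)c1ccc({R})cc1"),
    # aliphatic chains and rings
    c("CCCCC({R})CCO", "CC(C)CC({R})CC", "C1CCCCC1C{R}",
      "CCOC(=O)CC{R}", "CC(O)CC({R})CC", "OCCCCC({R})CO",
      "CCC(C)C({R})CC", "CC(N)CC({R})CO"),
    # heteroaromatics
    c("Cc1ccnc({R})c1", "CCc1cccnc1{R}", "Cc1occc1C{R}",
      "Cc1sccc1C{R}", "Cc1ccc(o1)C{R}", "CCc1ccc({R})o1",
      "Cc1cnccc1{R}", "Cc1csc(c1){R}"))
  lapply(fams, function(sc) {
    as.vector(vapply(sc, function(s)
      vapply(subs, function(r) sub("{R}", r, s, fixed = TRUE), ""),
      character(length(subs))))
  })
}

# community-biased random protein sequence
.random_protein <- function(len, community, n_communities, aa = amino_acids()) {
  w <- rep(1, 20)
  block <- split(seq_len(20), rep_len(seq_len(n_communities), 20))
  w[block[[((community - 1L) %% n_communities) + 1L]]] <- 5
  paste(sample(aa, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

.bernoulli_block <- function(comm_row, comm_col, p_in, p_out) {
  P <- outer(comm_row, comm_col, function(a, b) ifelse(a == b, p_in, p_out))
  M <- matrix(stats::rbinom(length(P), 1L, as.vector(P)), nrow(P), ncol(P))
  M
}

#' Generate a complete synthetic input bundle
#'
#' @param config A [synthetic_config()].
#' @return List of class `dti_bundle`: `drugs` (named SMILES vector),
#'   `proteins` (named residue strings), the six association matrices
#'   (`ddi`, `dti`, `drug_disease`, `drug_side_effect`, `tti`,
#'   `target_disease`), and the hidden community assignments
#'   (`communities`, for diagnostics only).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nc <- config$n_communities
  id <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  did <- id("d", config$n_drugs)
  tid <- id("t", config$n_targets)
  zid <- id("z", config$n_diseases)
  sid <- id("s", config$n_side_effects)
  cd <- rep_len(seq_len(nc), config$n_drugs)
  ct <- rep_len(seq_len(nc), config$n_targets)
  cz <- rep_len(seq_len(nc), config$n_diseases)
  cs <- rep_len(seq_len(nc), config$n_side_effects)

  tmpl <- .smiles_templates()
  drugs <- vapply(seq_len(config$n_drugs), function(i) {
    fam <- tmpl[[((cd[i] - 1L) %% length(tmpl)) + 1L]]
    sample(fam, 1L)
  }, "")
  names(drugs) <- did

  lens <- sample(seq(config$protein_length[1L], config$protein_length[2L]),
                 config$n_targets, replace = TRUE)
  proteins <- vapply(seq_len(config$n_targets), function(i)
    .random_protein(lens[i], ct[i], nc), "")
  names(proteins) <- tid

  sym <- function(M) { M <- pmax(M, t(M)); diag(M) <- 0L; M }
  dimn <- function(M, r, c) { dimnames(M) <- list(r, c); storage.mode(M) <- "integer"; M }
  ddi <- dimn(sym(.bernoulli_block(cd, cd, config$p_in, config$p_out)), did, did)
  tti <- dimn(sym(.bernoulli_block(ct, ct, config$p_in, config$p_out)), tid, tid)
  dti <- dimn(.bernoulli_block(cd, ct, config$p_in, config$p_out), did, tid)
  drug_disease <- dimn(.bernoulli_block(cd, cz, config$q_in, config$q_out),
                       did, zid)
  drug_side_effect <- dimn(.bernoulli_block(cd, cs, config$q_in, config$q_out),
                           did, sid)
  target_disease <- dimn(.bernoulli_block(ct, cz, config$q_in, config$q_out),
                         tid, zid)

  structure(list(drugs = drugs, proteins = proteins,
                 ddi = ddi, dti = dti, tti = tti,
                 drug_disease = drug_disease,
                 drug_side_effect = drug_side_effect,
                 target_disease = target_disease,
                 communities = list(drug = setNames(cd, did),
                                    target = setNames(ct, tid)),
                 config = config),
            class = "dti_bundle")
}

#' Write a bundle in the on-disk input layout
#'
#' FASTA protein sequences, a `drugs.tsv` SMILES table, one edge-list
#' TSV per association network, and a JSON manifest.
#'
#' @param bundle A `dti_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqinr::write.fasta(as.list(bundle$proteins), names(bundle$proteins),
                      file.path(dir, "proteins.fasta"), as.string = TRUE)
  utils::write.table(
    data.frame(drug_id = names(bundle$drugs), smiles = unname(bundle$drugs)),
    file.path(dir, "drugs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rels <- c("ddi", "dti", "tti", "drug_disease", "drug_side_effect",
            "target_disease")
  for (r in rels) {
    M <- bundle[[r]]
    idx <- which(M == 1L, arr.ind = TRUE)
    if (r %in% c("ddi", "tti")) idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    utils::write.table(
      data.frame(id_a = rownames(M)[idx[, 1L]], id_b = colnames(M)[idx[, 2L]]),
      file.path(dir, paste0(r, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(proteins = "proteins.fasta", drugs = "drugs.tsv",
         relations = as.list(setNames(paste0(rels, ".tsv"), rels)),
         disease_ids = colnames(bundle$drug_disease),
         side_effect_ids = colnames(bundle$drug_side_effect),
         seed = if (is.null(bundle$config)) NA else bundle$config$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a bundle written by [write_bundle()]
#' @param dir Directory containing `manifest.json`.
#' @return A `dti_bundle` (without community annotations).
#' @export
load_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  proteins <- read_protein_fasta(file.path(dir, man$proteins))
  drugs <- read_smiles_tsv(file.path(dir, man$drugs))
  did <- names(drugs); tid <- names(proteins)
  zid <- man$disease_ids; sid <- man$side_effect_ids
  rel <- function(f, rows, cols, symmetric = FALSE) {
    load_association(file.path(dir, f), rows, cols, symmetric = symmetric)
  }
  structure(list(
    drugs = drugs, proteins = proteins,
    ddi = rel(man$relations$ddi, did, did, symmetric = TRUE),
    dti = rel(man$relations$dti, did, tid),
    tti = rel(man$relations$tti, tid, tid, symmetric = TRUE),
    drug_disease = rel(man$relations$drug_disease, did, zid),
    drug_side_effect = rel(man$relations$drug_side_effect, did, sid),
    target_disease = rel(man$relations$target_disease, tid, zid),
    config = NULL), class = "dti_bundle")
}

#' Fixed micro-fixtures for unit tests and worked examples
#'
#' @return Named list: `kmer5` (5-residue protein), `jac` (two neighbour
#'   sets as a boolean matrix, rows sharing 2 of 4 neighbours), `fp`
#'   (two toy fingerprints with on-bits {1,3} and {2,3}), `graph2`
#'   (two-node single-edge adjacency).
#' @export
generate_worked_toys <- function() {
  jac <- matrix(c(1, 1, 1, 0,
                  0, 1, 1, 1), 2L, 4L, byrow = TRUE,
                dimnames = list(c("D1", "D2"), c("a", "b", "c", "d")))
  fp <- list(f1 = c(0, 1, 0, 1), f2 = c(0, 0, 1, 1))
  list(kmer5 = "ACDEG",
       jac = jac,
       fp = fp,
       graph2 = matrix(c(0, 1, 1, 0), 2L, 2L))
}
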