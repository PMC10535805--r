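---
title: "Methods: sequence + heterogeneous-network DTI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence + heterogeneous-network DTI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `hetdti`, the
assumptions behind it, the tunable parameters and their defaults, the
synthetic study conditions used by the tests, and the numerical and
design choices made where the problem statement was genuinely open.

## The model

`hetdti` scores drug–target pairs by combining two sources of evidence
that are individually standard in the DTI literature and here are
trained jointly:

* **Biological sequence features.** Each protein is tokenized into
  overlapping k-mers and one-hot encoded over the `20^k` canonical
  channel space; each drug SMILES string is tokenized into atoms,
  bonds, branches, ring digits and bracket atoms over a fixed 61-token
  vocabulary. A convolutional extractor — one linear window-3 "region"
  convolution with `N` kernels, two window-3 refinement convolutions
  that rectify their input before a cross-channel weighted sum, and two
  residual aggregation blocks `X_{t+1} = P(X_t) + θ(P(X_t))` with
  stride-2 max pooling `P` and a two-convolution map `θ` — halves the
  positional axis per block and a global max over unmasked positions
  yields one feature vector per entity. All convolutions are "valid"
  (length `L − 2`) except inside `θ`, which must be shape-preserving to
  be added to its pooled input and therefore uses zero same-padding.
* **Heterogeneous network structure.** The graph has drug and protein
  nodes only and five undirected typed relations: drug–drug
  interaction, drug–protein interaction, protein–protein interaction,
  and two *similarity* relations built by thresholding multi-source
  similarity scores. Disease and side-effect associations inform those
  scores but are not nodes; this keeps the relational encoder's
  aggregation restricted to the five relations it defines. Each GCN
  step propagates with the symmetrically normalised self-loop
  adjacency `A_r^{-1/2}(I + S_r)A_r^{-1/2}` per relation and sums
  rectified per-relation terms; the GAT step computes per-relation,
  per-head additive attention logits
  `LeakyReLU(aᵀ[W x_i ‖ W x_j ‖ B e_r])`, softmax-normalised over each
  node's neighbourhood under that relation, averages heads inside the
  rectifier and sums relations.

The stack is GCN → GAT → GCN. The published description of this
architecture is ambiguous about the ordering (the prose places one
attention layer between two convolution layers while the displayed
recursion stacks two attention layers first); we default to the prose
reading and expose the alternative as `layer_order = c("gat", "gat",
"gcn")`. To counter over-smoothing, the final representation fuses the
first- and third-layer outputs — never the second — through a learned
linear map of their concatenation (equivalently a window-1
convolution), which is dimension-preserving and parameter-light.

Training minimises the binary cross-entropy between known labels and
the logistic-squashed preference matrix `U = X_D X_Tᵀ`, jointly over
the convolutional and graph parameters, by full-batch Adam. Raw inner
products are unbounded, so the squash is applied inside the loss and
the probabilities are clamped at `1e-7` before the logarithm. The loss
runs over a *balanced resample* of the training pairs rather than all
`d_v × T_v` cells, matching the evaluation protocol's resampling; a
stratified 10% of training pairs is held out for early stopping.

The classifier is deliberately decoupled from representation learning:
fusion descriptors `Z_ij = [X_D(i), X_T(j)]` feed a 500-tree random
forest with `√p` candidate features per split. The `rf` ablation swaps
in a single-hidden-layer perceptron (decision threshold 0.5) to mimic
the end-to-end alternative; `bio` replaces the sequence features by
seeded random vectors; `het` bypasses the graph layers (descriptors
come directly from sequence features); `sim` drops both similarity
relations.

## Similarity scores

Drug pairs receive four scores; protein pairs three.

* **Network Jaccard** (three drug sources: disease, interaction,
  side-effect neighbourhoods; two protein sources): `J = N11 / (N01 +
  N10 + N11)` on the rows of each boolean association matrix. Two
  empty neighbourhoods score 0 — an entity with no recorded
  associations carries no evidence of similarity, not perfect
  similarity.
* **Fingerprint Tanimoto** (drugs): 167-bit MACCS structural keys via
  OpenBabel (bit 0 reserved, key `i` at 0-based position `i`),
  `T = N11 / (N01 + N10 − N11)`; all-zero fingerprints score 0.
  The backend is pluggable (`maccs_fingerprint(backend = ...)`) for
  other implementations of the public key set.
* **Sequence composition** (proteins): with lengths `S1`, `S2` and `E`
  the total absolute difference of per-residue-type counts,
  `I = |S1 − S2| + 2E` and `L = (S1 + S2 − I)/(S1 + S2)`. The name
  this score travels under elsewhere suggests an edit distance, but
  the printed formula contains none; we implement the formula, read
  `E` as the composition-difference term ("differences in the length
  and types of amino acids"), and isolate it in one function so an
  alternative reading is a one-line swap. `L` can go negative for
  highly dissimilar sequences, so it is clamped to `[0, 1]`.

A similarity edge joins a pair when *any* source score is strictly
greater than the threshold (default 0.5 for both entity kinds,
configurable per kind) and the pair has no recorded interaction.

## Parameters and defaults

| parameter | default | notes |
|---|---|---|
| `k` | 3 | k-mer width; channel space `20^k` (8000), corpus-restricted mode available |
| `L_D`, `L_T` | 95th-percentile corpus length, rounded up to a multiple of 8 | truncation from the right; zero-padding with masks |
| `n_kernels` (`N`) | 64 | feature width of every convolution and of the extracted vector |
| `n_blocks` | 2 | aggregation blocks; depth is 1 region + 2 refinement + the block convolutions |
| `d_hidden`, `d` | 128 | graph layer width and final embedding dimension |
| `K` | 4 | attention heads (averaged) |
| `db` | 8 | width of the learned edge-type embedding in the attention logit |
| `lr`, `epochs`, `patience` | 1e-3, 200, 20 | Adam, full batch, early stop on validation loss |
| `sim_threshold_*` | 0.5 | strict inequality |
| `balance_ratio` | 1 | positives : negatives after resampling |
| `rf_ntree` | 500 | `√p` features per split |

The balancing target size is the geometric mean of the two class
sizes: positives are duplicated with replacement *up* to it and
negatives sub-sampled without replacement *down* to it, so both
operations genuinely occur and an already-balanced set passes through
unchanged. Resampling is fit on training folds only; test folds are
never resampled, otherwise reported precision–recall areas would be
meaningless.

Unknown tokens: the 61-token SMILES vocabulary ends in an explicit
unknown token; protein vocabularies are canonical-only by default
(`size = 20^k` exactly) and gain a single unknown channel when built
with `unk = TRUE`, which the fitting pipeline does, so non-canonical
residues (B, J, O, U, X, Z) map to one shared channel. Policies
`error` and `drop` are available.

## Numerical choices

* Masks are carried through every extractor stage and re-applied
  inside the aggregation blocks (after pooling, after the first `θ`
  convolution and after the residual sum), so appending padding
  columns never changes a feature vector — including at the boundary
  where `θ`'s same-padding window would otherwise see values computed
  from padding.
* Max pooling breaks ties toward the earlier position; the global max
  routes gradients to the first attaining row.
* Attention softmax runs over the neighbourhood of `i` under the
  relation (the universal all-nodes reading is not useful on sparse
  relations and is not implemented); rows without neighbours produce
  zero attention and contribute zero — never NaN — to the layer
  output. Logits are max-shifted before exponentiation.
* An isolated node still propagates through GCN layers via its
  normalised self-loop (degree 1), so no relation ever divides by
  zero.
* The BCE backward pass uses the standard unclamped `(p − y)`
  subgradient while the loss *value* clamps probabilities at `1e-7`;
  finite-difference checks therefore probe unsaturated operating
  points.
* Gradients are exact reverse-mode derivatives computed on an
  operation tape; the test suite checks every composite against
  central differences and the batched extractor against the plain
  per-sequence path to 1e-12.
* Determinism: every random draw (initialisation, resampling, splits,
  forest) is seeded from the run configuration; two runs with the same
  seed produce bit-identical training curves and predictions.

## The synthetic study conditions

`synthetic_config()` defaults to 60 drugs, 90 targets, 150 diseases,
120 side effects and 3 latent communities. Drug–target, drug–drug and
target–target edges are Bernoulli(`p_in = 0.25`) within a community
and Bernoulli(`p_out = 0.02`) across; disease and side-effect
association profiles use 0.15/0.01, making the network Jaccard scores
community-informative. Drug SMILES are drawn from ~380 valid templates
organised into three chemical families (aromatic carbocycles,
aliphatics, heteroaromatics) aligned with the communities, so MACCS
Tanimoto similarity is informative; protein sequences of 40–100
residues use community-biased residue compositions, so the
composition score is informative. These sizes keep a full fit under
two minutes on one CPU; the test suite and the acceptance script use
them unchanged.

**What passing tests do and do not show.** The generator plants
*block* structure: given the community assignments, every drug–target
cell is an independent coin flip. No predictor, however good, can
separate positive from negative cells inside the same block, so the
attainable held-out AUC is capped at the block-posterior oracle —
about 0.79 at the default `(p_in, p_out) = (0.25, 0.02)` with three
communities, and about 0.86 at `p_in = 0.5`. Recovering the cap (the
pipeline measures ~0.73–0.78 at defaults and ~0.87 at `p_in = 0.5`;
`scripts/acceptance.R` recomputes these) demonstrates that the
embeddings recover the plantable signal, not that real benchmark
performance would reach any particular value. Real data differ in
ways the generator deliberately omits: heavy-tailed degree
distributions, correlated (non-iid) interactions within blocks,
sequence homology structure, chemically meaningful substituent
effects, and label noise from the positive-unlabelled convention.

The positive-unlabelled caveat applies to training as well: negatives
are sampled from `0` cells, which mean "unknown or no interaction";
scores should be read as rankings rather than calibrated
probabilities of true non-interaction.

## Evaluation protocols

`make_splits()` implements stratified random k-fold plus the three
cold-start protocols. Blind-drug folds partition drug ids so train and
test drug sets are disjoint (blind-protein symmetric); blind-pair
partitions both id sets, keeps test pairs with *both* ends held out
and discards mixed pairs from both sides — the strictest reading of
"no overlap", at the cost of evaluating fewer pairs. `audit_splits()`
re-checks the id-intersection invariants on every fold. Within
`run_cv()` each fold refits everything — the network's drug–protein
interaction edges are rebuilt from that fold's training positives
only — so no test label can leak through the graph. Evaluation metrics
are computed once per fold and averaged; repeated multi-run averaging
is available by looping seeds (the cross-validation report is
deterministic per seed).

## Known limitations

* Full-batch training on CPU targets desk-scale networks (hundreds of
  nodes); thousands of nodes would need mini-batching or sparse
  attention, neither of which is implemented.
* The protein similarity score is composition-based; alignment-based
  similarity (Smith–Waterman, BLAST) is out of scope.
* Probabilities from the forest are not calibrated.
* Interaction *type* (agonist/inhibitor/...) is not predicted.
* The OpenBabel structural-key backend is the only fingerprint
  implementation shipped; the `backend` hook exists for alternatives
  but key-by-key parity across implementations is only verified for
  the shipped one.
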