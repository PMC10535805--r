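# Command-line orchestration: subcommands composing the pipeline stages
# over an on-disk workspace, driven by a JSON run configuration with
# command-line overrides. Every artifact is stamped with the
# configuration hash and seed. The shipped entry point is
# inst/cli/hetdti.R.

.parse_cli_args <- function(args) {
  if (length(args) == 0L) stop(.cli_usage(), call. = FALSE)
  cmd <- args[1L]
  rest <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--")) stop(sprintf("unexpected argument '%s'", rest[i]))
    if (i == length(rest) || startsWith(rest[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- rest[i + 1L]
      i <- i + 2L
    }
  }
  list(cmd = cmd, opts = opts)
}

.cli_usage <- function() {
  paste(
    "usage: hetdti <command> [--key value ...]",
    "commands:",
    "  simulate   --out DIR [--seed N] [--config FILE]",
    "  featurize  --bundle DIR --out DIR [--config FILE]",
    "  build-net  --bundle DIR --out DIR [--config FILE]",
    "  train      --bundle DIR --out DIR [--config FILE] [--ablate a,b]",
    "  predict    --model FILE --pairs TSV --out TSV",
    "  evaluate   --bundle DIR --out DIR [--mode MODE] [--folds K]",
    "             [--max-folds M] [--ablate a,b] [--config FILE]",
    sep = "\n")
}

.load_run_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) {
    vals <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    do.call(dti_config, vals)
  } else {
    dti_config()
  }
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg
}

.config_hash <- function(cfg) {
  # order-independent structural hash; avoids a digest dependency
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

.stamp <- function(dir, cfg, extra = list()) {
  jsonlite::write_json(c(list(config_hash = .config_hash(cfg),
                              seed = cfg$seed), extra),
                       file.path(dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.ablate_opt <- function(opts) {
  if (is.null(opts$ablate)) character(0)
  else strsplit(opts$ablate, ",")[[1L]]
}

#' Command-line pipeline entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `featurize`
#' (vocabularies and sequence-embedding summary), `build-net`
#' (similarity edges + network serialization), `train` (fit and save a
#' model), `predict` (score a pair list with a saved model), `evaluate`
#' (cross-validated AUC/AUPR report). Run with no arguments for usage.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
dti_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- .parse_cli_args(args)
  cmd <- parsed$cmd
  opts <- parsed$opts
  cfg <- .load_run_config(opts)

  need <- function(key) {
    if (is.null(opts[[key]])) stop(sprintf("--%s is required for '%s'", key, cmd))
    opts[[key]]
  }

  if (cmd == "simulate") {
    out <- need("out")
    scfg <- synthetic_config(seed = cfg$seed)
    bundle <- generate_dataset(scfg)
    write_bundle(bundle, out)
    dir.create(out, showWarnings = FALSE)
    .stamp(out, cfg, list(stage = "simulate"))
    message(sprintf("wrote synthetic bundle (%d drugs, %d proteins) to %s",
                    length(bundle$drugs), length(bundle$proteins), out))
  } else if (cmd == "featurize") {
    bundle <- load_bundle(need("bundle"))
    out <- need("out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    pv <- build_kmer_vocabulary(bundle$proteins, k = cfg$k,
                                mode = cfg$vocab_mode, unk = cfg$unk)
    sv <- default_smiles_vocabulary()
    write_vocabulary_json(pv, file.path(out, "protein_vocab.json"))
    write_vocabulary_json(sv, file.path(out, "smiles_vocab.json"))
    d_len <- lengths(lapply(bundle$drugs, tokenize_smiles))
    p_len <- nchar(bundle$proteins) - cfg$k + 1L
    jsonlite::write_json(
      list(L_D = default_padded_length(d_len),
           L_T = default_padded_length(p_len),
           C_drug = sv$size, C_protein = pv$size),
      file.path(out, "embedding_dims.json"), auto_unbox = TRUE)
    .stamp(out, cfg, list(stage = "featurize"))
  } else if (cmd == "build-net") {
    bundle <- load_bundle(need("bundle"))
    out <- need("out")
    d_edges <- add_similarity_edges(.drug_similarities(bundle),
                                    cfg$sim_threshold_drug, bundle$ddi)
    p_edges <- add_similarity_edges(.target_similarities(bundle),
                                    cfg$sim_threshold_protein, bundle$tti)
    net <- assemble_network(names(bundle$drugs), names(bundle$proteins),
                            bundle$ddi, bundle$dti, bundle$tti,
                            d_edges, p_edges)
    validate_network(net)
    save_network(net, out)
    write_edges_tsv(d_edges, file.path(out, "drug_similarity_scores.tsv"))
    write_edges_tsv(p_edges, file.path(out, "protein_similarity_scores.tsv"))
    .stamp(out, cfg, list(stage = "build-net"))
  } else if (cmd == "train") {
    bundle <- load_bundle(need("bundle"))
    out <- need("out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    fit <- dti_fit(bundle, cfg, ablate = .ablate_opt(opts))
    saveRDS(fit, file.path(out, "model.rds"))
    utils::write.csv(fit$log, file.path(out, "training_log.csv"),
                     row.names = FALSE)
    .stamp(out, cfg, list(stage = "train", ablate = .ablate_opt(opts)))
  } else if (cmd == "predict") {
    fit <- readRDS(need("model"))
    pairs <- utils::read.delim(need("pairs"), stringsAsFactors = FALSE,
                               colClasses = "character")
    names(pairs)[1:2] <- c("drug", "protein")
    pr <- predict(fit, pairs)
    utils::write.table(pr, need("out"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (cmd == "evaluate") {
    bundle <- load_bundle(need("bundle"))
    out <- need("out")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    k <- if (is.null(opts$folds)) 5L else as.integer(opts$folds)
    mf <- if (is.null(opts[["max-folds"]])) k else as.integer(opts[["max-folds"]])
    mode <- if (is.null(opts$mode)) "random" else opts$mode
    cv <- run_cv(bundle, cfg, mode = mode, k = k, max_folds = mf,
                 ablate = .ablate_opt(opts))
    utils::write.csv(cv$report, file.path(out, "report.csv"),
                     row.names = FALSE)
    mrow <- cv$report[is.na(cv$report$fold), ]
    jsonlite::write_json(list(mode = mode, auc = mrow$auc, aupr = mrow$aupr),
                         file.path(out, "summary.json"), auto_unbox = TRUE)
    .stamp(out, cfg, list(stage = "evaluate", mode = mode))
    print(cv)
  } else {
    stop(.cli_usage(), call. = FALSE)
  }
  invisible(0L)
}
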