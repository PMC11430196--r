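# End-to-end experiment orchestration: simulate or load a corpus, split
# it by sequence, fit the encoder on the training split, train the
# requested families, score the test split, and (optionally) run the
# importance and ablation analyses, writing every artifact plus a
# manifest recording seeds, config hash and package version.

#' Build and validate an experiment configuration
#'
#' @param generator A [generator_config()] (used when `data` is `NULL`).
#' @param data Optional list with paths `fasta`, `labels`, and optionally
#'   `pssm_dir` (one `<id>.pssm` file per sequence); when given, the
#'   corpus is loaded instead of simulated.
#' @param task `"three_state"` or `"eight_state"`.
#' @param factors,window Feature schema, see [feature_schema()].
#' @param families Classifier families to run.
#' @param train_fraction,seed Grouped split parameters.
#' @param sov_norm Sov normalizer, see [sov()].
#' @param importance_repeats Permutation repeats for the per-family
#'   importance analysis; 0 skips it.
#' @param ablation If `TRUE`, also run [run_ablation()] with
#'   onehot+pssm as base and properties+trend added.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(generator = generator_config(),
                              data = NULL,
                              task = c("three_state", "eight_state"),
                              factors = c("onehot", "pssm", "properties",
                                          "trend"),
                              window = 13,
                              families = ss_families(),
                              train_fraction = 0.7,
                              seed = 1,
                              sov_norm = "length",
                              importance_repeats = 0,
                              ablation = FALSE) {
  task <- match.arg(task)
  families <- match.arg(families, several.ok = TRUE)
  if (!is.null(data)) {
    if (!all(c("fasta", "labels") %in% names(data))) {
      stop("`data` must name at least `fasta` and `labels` paths")
    }
  } else {
    stopifnot(inherits(generator, "generator_config"))
    if (generator$alphabet != task) {
      stop("generator alphabet (", generator$alphabet,
           ") does not match task (", task, ")")
    }
  }
  stopifnot(train_fraction > 0, train_fraction < 1,
            importance_repeats >= 0)
  structure(list(generator = generator, data = data, task = task,
                 factors = factors, window = window, families = families,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 sov_norm = sov_norm,
                 importance_repeats = as.integer(importance_repeats),
                 ablation = isTRUE(ablation)),
            class = "experiment_config")
}

#' Serialize / restore an experiment configuration
#'
#' `write_experiment_config()` writes the configuration (including the
#' generator's transition and emission matrices) as YAML;
#' `read_experiment_config()` reconstructs and re-validates it. The round
#' trip is lossless.
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config()` returns `path` invisibly;
#'   `read_experiment_config()` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  g <- config$generator
  gen <- if (is.null(g)) NULL else list(
    n_sequences = g$n_sequences,
    length_range = as.integer(g$length_range),
    alphabet = g$alphabet,
    transition = apply(g$transition, 1, as.list, simplify = FALSE),
    emission = apply(g$emission, 1, as.list, simplify = FALSE),
    pssm_noise = g$pssm_noise,
    pssm_context = g$pssm_context,
    seed = g$seed)
  yaml::write_yaml(list(
    generator = gen, data = config$data, task = config$task,
    factors = as.list(config$factors), window = config$window,
    families = as.list(config$families),
    train_fraction = config$train_fraction, seed = config$seed,
    sov_norm = config$sov_norm,
    importance_repeats = config$importance_repeats,
    ablation = config$ablation), path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(x$generator)) {
    g <- x$generator
    to_matrix <- function(rows) {
      m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
      rownames(m) <- names(rows)
      m
    }
    gen <- generator_config(
      n_sequences = g$n_sequences, length_range = unlist(g$length_range),
      alphabet = g$alphabet, transition = to_matrix(g$transition),
      emission = to_matrix(g$emission), pssm_noise = g$pssm_noise,
      pssm_context = g$pssm_context, seed = g$seed)
  }
  experiment_config(
    generator = if (is.null(gen)) generator_config() else gen,
    data = x$data, task = x$task, factors = unlist(x$factors),
    window = x$window, families = unlist(x$families),
    train_fraction = x$train_fraction, seed = x$seed,
    sov_norm = x$sov_norm, importance_repeats = x$importance_repeats,
    ablation = x$ablation)
}

#' Load a corpus from FASTA, label and PSSM files
#'
#' Joins sequences, per-residue labels and (optionally) one PSSM file per
#' sequence by record id, checking residue-level alignment throughout.
#'
#' @param fasta Path to the sequence FASTA.
#' @param labels Path to the FASTA-like label file.
#' @param pssm_dir Optional directory of `<id>.pssm` files.
#' @param alphabet Label alphabet.
#' @param strict Passed to [read_fasta()].
#' @return A corpus tibble like [simulate_corpus()]'s (without a config
#'   attribute).
#' @export
load_corpus <- function(fasta, labels, pssm_dir = NULL,
                        alphabet = c("three_state", "eight_state"),
                        strict = FALSE) {
  alphabet <- match.arg(alphabet)
  recs <- read_fasta(fasta, strict = strict)
  labs <- read_ss_labels(labels, alphabet)
  out <- dplyr::inner_join(recs, labs, by = "id")
  if (nrow(out) == 0) stop("no records shared between ", fasta, " and ", labels)
  bad <- nchar(out$sequence) != nchar(out$labels)
  if (any(bad)) {
    stop("sequence/label length mismatch for '", out$id[which(bad)[1]], "'")
  }
  if (!is.null(pssm_dir)) {
    out$pssm <- purrr::map2(out$id, out$sequence, function(id, s) {
      path <- file.path(pssm_dir, paste0(id, ".pssm"))
      read_pssm_ascii(path, sequence = s, id = id)
    })
  }
  attr(out, "alphabet") <- alphabet
  out
}

#' Run a full experiment from a configuration
#'
#' Simulates or loads the corpus, performs a grouped train/test split,
#' fits the feature encoder on the training split (trend table, property
#' scaling), trains every requested family, evaluates Q and Sov on the
#' test split, optionally computes grouped importance and the factor
#' ablation, and writes all artifacts under `out_dir`: the fitted trend
#' table (`trend_table.csv` + sidecar), per-family prediction label files
#' and evaluation JSONs, a `metrics.csv` summary, importance and ablation
#' CSVs when requested, and `manifest.json` with the seed, config hash
#' and package version. Identical configurations produce byte-identical
#' artifacts.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the corpus split, encoder, models,
#'   evaluations, metrics tibble, and importance/ablation results.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  corpus <- if (is.null(config$data)) {
    simulate_corpus(config$generator)
  } else {
    load_corpus(config$data$fasta, config$data$labels,
                config$data$pssm_dir, alphabet = config$task)
  }
  sp <- split_corpus(corpus, config$train_fraction, config$seed)
  schema <- feature_schema(config$factors, window = config$window,
                           alphabet = config$task)
  enc <- fit_encoder(sp$train, schema)
  if (!is.null(enc$trend)) {
    write_trend_table(enc$trend, file.path(out_dir, "trend_table.csv"))
  }
  tr <- encode_corpus(enc, sp$train)
  te <- encode_corpus(enc, sp$test)

  models <- list()
  evals <- list()
  metrics <- list()
  importance <- list()
  for (fam in config$families) {
    m <- train_ss_model(tr, fam, seed = config$seed)
    pred <- predict(m, te$X)
    pred_tbl <- dataset_labels(te, pred)
    write_fasta(pred_tbl, file.path(out_dir, paste0("pred_", fam, ".fasta")))
    ev <- evaluate_ss(sp$test$labels, pred_tbl$labels,
                      alphabet = config$task, sov_norm = config$sov_norm)
    jsonlite::write_json(
      list(family = fam, q = ev$q, sov_overall = ev$sov_overall,
           sov_per_state = as.list(ev$sov_per_state),
           n_residues = ev$n_residues,
           confusion = as.data.frame(as.table(ev$confusion))),
      file.path(out_dir, paste0("evaluation_", fam, ".json")),
      auto_unbox = TRUE, digits = NA)
    models[[fam]] <- m
    evals[[fam]] <- ev
    metrics[[fam]] <- tibble::tibble(family = fam, q = ev$q,
                                     sov = ev$sov_overall,
                                     n_residues = ev$n_residues)
    if (config$importance_repeats > 0) {
      imp <- grouped_importance(m, te, repeats = config$importance_repeats,
                                seed = config$seed)
      importance[[fam]] <- imp
      utils::write.csv(
        cbind(family = fam, as.data.frame(imp$per_factor)),
        file.path(out_dir, paste0("importance_", fam, ".csv")),
        row.names = FALSE)
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  utils::write.csv(as.data.frame(metrics),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)

  ablation <- NULL
  if (config$ablation) {
    ablation <- run_ablation(corpus, families = config$families,
                             window = config$window,
                             train_fraction = config$train_fraction,
                             seed = config$seed,
                             sov_norm = config$sov_norm)
    utils::write.csv(as.data.frame(
      dplyr::left_join(tidyr::pivot_wider(ablation$results,
                                          names_from = "arm",
                                          values_from = c("q", "sov")),
                       ablation$deltas, by = "family")),
      file.path(out_dir, "ablation.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "ssfactors",
    version = as.character(utils::packageVersion("ssfactors")),
    seed = config$seed,
    task = config$task,
    factors = config$factors,
    window = config$window,
    families = config$families,
    train_fraction = config$train_fraction,
    config_hash = rlang::hash(config),
    n_sequences = nrow(corpus),
    n_train_sequences = nrow(sp$train),
    n_test_sequences = nrow(sp$test))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(corpus = corpus, split = sp, encoder = enc,
                 models = models, evaluations = evals, metrics = metrics,
                 importance = importance, ablation = ablation,
                 manifest = manifest))
}

#' Write a small demonstration corpus to disk
#'
#' Simulates a seeded mini-corpus and writes it in the three on-disk
#' formats the readers consume (FASTA sequences, FASTA-like labels, one
#' PSI-BLAST-dialect PSSM file per sequence) — a self-contained fixture
#' factory for examples and tests.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_sequences,length_range,seed Generator settings for the
#'   mini-corpus.
#' @param alphabet Label alphabet.
#' @return Invisibly, a list with the written paths (`fasta`, `labels`,
#'   `pssm_dir`) and the corpus tibble.
#' @export
make_fixtures <- function(out_dir, n_sequences = 6,
                          length_range = c(30, 60), seed = 42,
                          alphabet = "three_state") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- generator_config(n_sequences = n_sequences,
                          length_range = length_range,
                          alphabet = alphabet, seed = seed)
  corpus <- simulate_corpus(cfg)
  fasta <- file.path(out_dir, "sequences.fasta")
  labels <- file.path(out_dir, "labels.fasta")
  pssm_dir <- file.path(out_dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  write_fasta(corpus[, c("id", "sequence")], fasta)
  write_fasta(corpus[, c("id", "labels")], labels)
  for (i in seq_len(nrow(corpus))) {
    write_pssm_ascii(corpus$pssm[[i]],
                     file.path(pssm_dir, paste0(corpus$id[i], ".pssm")))
  }
  invisible(list(fasta = fasta, labels = labels, pssm_dir = pssm_dir,
                 corpus = corpus))
}
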