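# Factor ablation: the same split, seed and model settings are run twice,
# once on a base feature set (sequence one-hot + PSSM, the conventional
# inputs) and once with the property and trend factors added, and the
# paired Q/Sov reports are differenced.

#' Factor ablation experiment
#'
#' Splits the corpus once (grouped by sequence), then for each classifier
#' family trains and evaluates two arms under identical seeds: the base
#' factor set and the base plus the added factors. Reports each arm's Q
#' and Sov and their differences (with-factors minus without).
#'
#' @param corpus A labelled corpus tibble (see [simulate_corpus()]).
#' @param families Classifier families to run.
#' @param base_factors Factors of the base arm.
#' @param added_factors Factors added in the augmented arm.
#' @param window Window length for both arms.
#' @param train_fraction,seed Grouped split parameters (shared by both
#'   arms).
#' @param sov_norm Sov normalizer, see [sov()].
#' @param ... Passed to [train_ss_model()] (e.g. `subsample_cap`).
#' @return An `ss_ablation` object: list with `results` (tibble: `family`,
#'   `arm`, `q`, `sov`), `deltas` (tibble: `family`, `delta_q`,
#'   `delta_sov`), and `reports` (nested list of `ss_evaluation`s).
#' @examples
#' \donttest{
#' co <- simulate_corpus(generator_config(n_sequences = 30,
#'                                        length_range = c(40, 80), seed = 5))
#' ab <- run_ablation(co, families = "naive_bayes", window = 5)
#' ab$deltas
#' }
#' @export
run_ablation <- function(corpus,
                         families = ss_families(),
                         base_factors = c("onehot", "pssm"),
                         added_factors = c("properties", "trend"),
                         window = 13,
                         train_fraction = 0.7,
                         seed = 1,
                         sov_norm = "length",
                         ...) {
  alphabet <- attr(corpus, "alphabet")
  if (is.null(alphabet)) stop("corpus carries no alphabet attribute")
  sp <- split_corpus(corpus, train_fraction, seed)
  arms <- list(
    without = base_factors,
    with = unique(c(base_factors, added_factors))
  )
  obs_test <- NULL
  reports <- list()
  rows <- list()
  for (arm in names(arms)) {
    schema <- feature_schema(arms[[arm]], window = window,
                             alphabet = alphabet)
    enc <- fit_encoder(sp$train, schema)
    tr <- encode_corpus(enc, sp$train)
    te <- encode_corpus(enc, sp$test)
    obs_test <- sp$test$labels
    for (fam in families) {
      m <- train_ss_model(tr, fam, ..., seed = seed)
      pred <- predict(m, te$X)
      ev <- evaluate_ss(obs_test, regroup_predictions(pred, te$groups),
                        alphabet = alphabet, sov_norm = sov_norm)
      reports[[fam]][[arm]] <- ev
      rows[[length(rows) + 1]] <- tibble::tibble(
        family = fam, arm = arm, q = ev$q, sov = ev$sov_overall)
    }
  }
  results <- dplyr::bind_rows(rows)
  deltas <- results |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("q", "sov")) |>
    dplyr::mutate(delta_q = .data$q_with - .data$q_without,
                  delta_sov = .data$sov_with - .data$sov_without) |>
    dplyr::select("family", "delta_q", "delta_sov")
  structure(list(results = results, deltas = deltas, reports = reports,
                 base_factors = base_factors,
                 added_factors = added_factors,
                 window = window, seed = seed),
            class = "ss_ablation")
}

#' @export
print.ss_ablation <- function(x, ...) {
  cat("Factor ablation: base = ", paste(x$base_factors, collapse = "+"),
      "; added = ", paste(x$added_factors, collapse = "+"), "\n", sep = "")
  print(as.data.frame(dplyr::left_join(
    tidyr::pivot_wider(x$results, names_from = "arm",
                       values_from = c("q", "sov")),
    x$deltas, by = "family")), digits = 4)
  invisible(x)
}

#' @export
tidy.ss_ablation <- function(x, ...) x$results

#' @export
glance.ss_ablation <- function(x, ...) x$deltas
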