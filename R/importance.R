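# Grouped permutation importance: credit is attributed to a whole factor
# (all columns of its block, across every window position) by permuting
# the block jointly over evaluation rows and measuring the drop in Q
# accuracy. Model-agnostic, so it applies uniformly to all four
# classifier families.

#' Grouped permutation importance of the feature factors
#'
#' For each factor of the model's schema, permutes (jointly, with one row
#' permutation per repeat) all of that factor's columns in the evaluation
#' set, re-predicts, and records the drop in Q accuracy relative to the
#' unpermuted baseline. Drops are averaged over repeats, floored at zero
#' (a permutation can raise accuracy by chance; negative drops carry no
#' evidence of importance) and normalized to shares summing to 100.
#'
#' Run this on held-out data: on the training set the drops reflect
#' memorization as much as signal.
#'
#' @param model An [train_ss_model()] fit.
#' @param dataset A labelled `windowed_dataset` whose schema matches the
#'   model's (normally the test split).
#' @param repeats Number of permutation repeats per factor.
#' @param seed Integer seed for the permutations.
#' @return An `importance_report`: list with `per_factor` (tibble:
#'   `factor`, `raw_drop`, `floored_drop`, `share`), `baseline_q`,
#'   `method`, `repeats`, `seed`.
#' @examples
#' ds <- simulate_factor_dataset(generator_config(n_sequences = 8, seed = 4))
#' sp <- split_dataset(ds, seed = 4)
#' m <- train_ss_model(sp$train, "naive_bayes")
#' grouped_importance(m, sp$test, repeats = 3, seed = 4)
#' @export
grouped_importance <- function(model, dataset, repeats = 20, seed = 1) {
  stopifnot(inherits(model, "ss_model"),
            inherits(dataset, "windowed_dataset"))
  schema <- model$schema
  if (length(schema$factors) < 2) {
    stop("importance is undefined for a single-factor schema")
  }
  if (ncol(dataset$X) != schema$total_width) {
    stop("dataset width does not match the model's schema")
  }
  if (is.null(dataset$y)) stop("dataset has no labels")
  baseline_q <- q_accuracy(dataset$y, predict(model, dataset$X))
  n <- nrow(dataset$X)
  set.seed(seed)
  perms <- purrr::map(seq_len(repeats), function(r) sample.int(n))
  raw_drop <- vapply(schema$factors, function(f) {
    cols <- factor_columns(schema, f)
    drops <- vapply(perms, function(perm) {
      Xp <- dataset$X
      Xp[, cols] <- Xp[perm, cols]
      baseline_q - q_accuracy(dataset$y, predict(model, Xp))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  floored <- pmax(raw_drop, 0)
  if (sum(floored) == 0) {
    warning("no factor permutation reduced accuracy; shares set equal")
    share <- rep(100 / length(floored), length(floored))
  } else {
    share <- 100 * floored / sum(floored)
  }
  structure(list(
    per_factor = tibble::tibble(factor = schema$factors,
                                raw_drop = unname(raw_drop),
                                floored_drop = unname(floored),
                                share = unname(share)),
    baseline_q = baseline_q,
    method = "grouped permutation importance (Q drop, held-out)",
    repeats = repeats, seed = seed, family = model$family),
    class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Grouped permutation importance (", x$family, ", baseline Q = ",
      sprintf("%.2f", x$baseline_q), "%, ", x$repeats, " repeats)\n",
      sep = "")
  print(as.data.frame(x$per_factor), digits = 4)
  invisible(x)
}

#' @export
tidy.importance_report <- function(x, ...) x$per_factor

#' @export
glance.importance_report <- function(x, ...) {
  tibble::tibble(family = x$family, baseline_q = x$baseline_q,
                 repeats = x$repeats, seed = x$seed)
}
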