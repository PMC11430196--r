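# Per-residue factor encodings and their assembly into sliding-window
# feature vectors. Four factors are supported: sequence one-hot (20),
# PSSM log-odds (20, logistic-squashed by default), physicochemical
# properties (4) and trend factors (|states|). A window of w residues
# concatenates the per-position blocks of the w/2 neighbours on each side,
# with all-zero padding beyond the termini.

#' One-hot encode an amino-acid sequence
#'
#' @param sequence An amino-acid sequence string over the standard
#'   20-letter alphabet.
#' @return An `n x 20` binary matrix; row i has a single 1 at the canonical
#'   column of residue i (see [aa_alphabet()]).
#' @examples
#' onehot_encode("ACD")
#' @export
onehot_encode <- function(sequence) {
  ch <- seq_chars(sequence)
  idx <- match(ch, aa_alphabet())
  if (anyNA(idx)) {
    stop("residue '", ch[which(is.na(idx))[1]], "' is not a standard amino acid")
  }
  m <- matrix(0, nrow = length(ch), ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Scale a PSSM into a per-residue feature block
#'
#' PSI-BLAST log-odds are unbounded; the default logistic squashing
#' `1 / (1 + exp(-x))` maps them into \\[0, 1\\] so the PSSM factor shares
#' scale with the other factors (KNN and SVM are distance/scale
#' sensitive). `scaling = "none"` returns the raw scores.
#'
#' @param pssm An `n x 20` PSSM matrix in canonical column order, e.g.
#'   from [read_pssm_ascii()] or [simulate_corpus()].
#' @param scaling `"sigmoid"` (default) or `"none"`.
#' @return An `n x 20` numeric matrix.
#' @examples
#' pssm_encode(matrix(0, 1, 20))[1, 1]  # sigmoid(0) = 0.5
#' @export
pssm_encode <- function(pssm, scaling = c("sigmoid", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(ncol(pssm) == 20)
  m <- unclass(pssm)
  attr(m, "id") <- NULL
  attr(m, "residues") <- NULL
  if (scaling == "sigmoid") m <- 1 / (1 + exp(-m))
  m
}

#' Concatenate per-residue features over a sliding window
#'
#' Row i of the output is the concatenation of feature rows
#' i-w, ..., i, ..., i+w (w = (window-1)/2), with all-zero rows standing in
#' for positions beyond the sequence termini.
#'
#' @param features An `n x d` per-residue feature matrix.
#' @param window Odd positive window length in residues; `window = 1` is
#'   the identity.
#' @return An `n x (window * d)` matrix.
#' @examples
#' build_windows(matrix(c(5, 7), ncol = 1), window = 3)
#' @export
build_windows <- function(features, window) {
  if (length(window) != 1 || window < 1 || window %% 2 != 1) {
    stop("`window` must be an odd positive integer")
  }
  features <- as.matrix(features)
  if (window == 1) {
    dimnames(features) <- NULL
    return(features)
  }
  n <- nrow(features)
  d <- ncol(features)
  w <- (window - 1) / 2
  pad <- matrix(0, w, d)
  padded <- rbind(pad, features, pad)
  out <- do.call(cbind, lapply(seq_len(window), function(p) {
    padded[seq_len(n) + p - 1, , drop = FALSE]
  }))
  dimnames(out) <- NULL
  out
}

factor_width <- function(factor, n_states) {
  switch(factor,
         onehot = 20L, pssm = 20L, properties = 4L,
         trend = as.integer(n_states),
         stop("unknown factor '", factor, "'"))
}

#' Declare the factor layout of a windowed feature vector
#'
#' A schema fixes which factors are present, their order, the window
#' length and the state alphabet, and records where each factor's columns
#' live in the assembled vector — which is what lets the evaluation code
#' permute or drop whole factors.
#'
#' @param factors Ordered subset of `"onehot"`, `"pssm"`, `"properties"`,
#'   `"trend"`.
#' @param window Odd positive window length (residues). The default, 13,
#'   is a standard context size in secondary-structure prediction.
#' @param alphabet `"three_state"` or `"eight_state"` (sets the trend
#'   factor's width and the label alphabet).
#' @param pssm_scaling Passed to [pssm_encode()].
#' @param property_scaling `"minmax"` (default: rescale each property
#'   column to \\[0, 1\\] by the fixed range of the shipped property table,
#'   so all four factors share scale in the Euclidean metric), `"zscore"`
#'   (z-score with training-split statistics) or `"none"`.
#' @return A `feature_schema` object with the per-position column ranges,
#'   per-position width and total width.
#' @examples
#' feature_schema()  # onehot+pssm+properties+trend, window 13: width 611
#' @export
feature_schema <- function(factors = c("onehot", "pssm", "properties", "trend"),
                           window = 13,
                           alphabet = c("three_state", "eight_state"),
                           pssm_scaling = c("sigmoid", "none"),
                           property_scaling = c("minmax", "zscore", "none")) {
  alphabet <- match.arg(alphabet)
  pssm_scaling <- match.arg(pssm_scaling)
  property_scaling <- match.arg(property_scaling)
  factors <- match.arg(factors, several.ok = TRUE)
  if (length(window) != 1 || window < 1 || window %% 2 != 1) {
    stop("`window` must be an odd positive integer")
  }
  n_states <- length(ss_alphabet(alphabet))
  widths <- vapply(factors, factor_width, integer(1), n_states = n_states)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ranges <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(ranges) <- factors
  structure(list(factors = factors, window = as.integer(window),
                 alphabet = alphabet, pssm_scaling = pssm_scaling,
                 property_scaling = property_scaling,
                 column_ranges = ranges,
                 per_position_width = sum(widths),
                 total_width = as.integer(window) * sum(widths)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema: ", paste(x$factors, collapse = " + "),
      " | window ", x$window, " | ", x$alphabet,
      " | ", x$total_width, " columns\n", sep = "")
  invisible(x)
}

#' Columns of one factor in the windowed feature matrix
#'
#' @param schema A [feature_schema()].
#' @param factor One of the schema's factors.
#' @return Integer vector of column indices (all window positions of the
#'   factor's block).
#' @export
factor_columns <- function(schema, factor) {
  r <- schema$column_ranges[[factor]]
  if (is.null(r)) stop("factor '", factor, "' is not in the schema")
  offsets <- (seq_len(schema$window) - 1L) * schema$per_position_width
  as.vector(outer(seq.int(r["start"], r["end"]), offsets, "+"))
}

#' Fit the data-dependent parts of a feature encoder
#'
#' Fits everything the schema's factors need that must come from the
#' training split only: the trend-factor table (which consumes labels) and
#' the property z-score statistics. The returned encoder is applied frozen
#' to any corpus with [encode_corpus()], so no label or distributional
#' information can leak from held-out data into the features.
#'
#' @param corpus A training corpus tibble (see [simulate_corpus()]).
#' @param schema A [feature_schema()].
#' @param property_table Property table for the `properties` factor.
#' @return An `ss_encoder` object.
#' @examples
#' co <- simulate_corpus(generator_config(n_sequences = 5, seed = 1))
#' enc <- fit_encoder(co, feature_schema(window = 3))
#' ds <- encode_corpus(enc, co)
#' dim(ds$X)
#' @export
fit_encoder <- function(corpus, schema = feature_schema(),
                        property_table = aa_property_table()) {
  stopifnot(inherits(schema, "feature_schema"))
  trend <- NULL
  if ("trend" %in% schema$factors) {
    trend <- fit_trend_table(corpus, alphabet = schema$alphabet)
  }
  prop_scaling <- NULL
  if ("properties" %in% schema$factors) {
    prop_scaling <- switch(schema$property_scaling,
      zscore = fit_property_scaling(corpus, property_table),
      minmax = minmax_property_scaling(property_table),
      none = NULL)
  }
  structure(list(schema = schema, trend = trend,
                 property_scaling = prop_scaling,
                 property_table = property_table),
            class = "ss_encoder")
}

#' Assemble a corpus into a windowed per-residue dataset
#'
#' For every sequence, builds the per-position factor blocks named in the
#' encoder's schema (in schema order), concatenates them, applies the
#' sliding window, and stacks all sequences into one feature matrix with
#' residue-aligned labels and per-row sequence ids (for grouped
#' splitting).
#'
#' @param encoder An [fit_encoder()] object.
#' @param corpus A corpus tibble; must have `sequence`, and `labels` when
#'   present are carried into the dataset; a `pssm` list-column is
#'   required when the schema includes the pssm factor.
#' @return A `windowed_dataset`: list with matrix `X`
#'   (residues x total_width), character vector `y` (or `NULL`), character
#'   vector `groups` (sequence id per row) and the `schema`.
#' @export
encode_corpus <- function(encoder, corpus) {
  stopifnot(inherits(encoder, "ss_encoder"))
  schema <- encoder$schema
  if ("trend" %in% schema$factors && is.null(encoder$trend)) {
    stop("encoder has no fitted trend table")
  }
  if ("pssm" %in% schema$factors && !("pssm" %in% names(corpus))) {
    stop("schema includes the pssm factor but the corpus has no pssm column")
  }
  blocks <- purrr::map(seq_len(nrow(corpus)), function(i) {
    seqs <- corpus$sequence[i]
    per_pos <- purrr::map(schema$factors, function(f) {
      switch(f,
        onehot = onehot_encode(seqs),
        pssm = {
          p <- corpus$pssm[[i]]
          if (is.null(p)) stop("missing PSSM for sequence '",
                               corpus$id[i], "'")
          if (nrow(p) != nchar(seqs)) {
            stop("PSSM rows (", nrow(p), ") do not match sequence length (",
                 nchar(seqs), ") for '", corpus$id[i], "'")
          }
          pssm_encode(p, schema$pssm_scaling)
        },
        properties = property_encode(seqs, encoder$property_table,
                                     scaling = encoder$property_scaling),
        trend = trend_encode(seqs, encoder$trend))
    })
    build_windows(do.call(cbind, per_pos), schema$window)
  })
  X <- do.call(rbind, blocks)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- NULL
  if ("labels" %in% names(corpus)) {
    y <- unlist(strsplit(paste(corpus$labels, collapse = ""), ""))
  }
  groups <- rep(corpus$id, nchar(corpus$sequence))
  structure(list(X = X, y = y, groups = groups, schema = schema),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat("Windowed dataset: ", nrow(x$X), " residues x ", ncol(x$X),
      " features (", paste(x$schema$factors, collapse = "+"),
      ", window ", x$schema$window, "), ",
      length(unique(x$groups)), " sequences\n", sep = "")
  invisible(x)
}

#' Remove a whole factor from a windowed dataset
#'
#' Drops exactly the columns recorded for `factor` in the schema and
#' returns a dataset whose schema describes the remaining factors.
#'
#' @param dataset A `windowed_dataset`.
#' @param factor Factor name to drop.
#' @return A `windowed_dataset` without that factor.
#' @export
drop_factor <- function(dataset, factor) {
  schema <- dataset$schema
  cols <- factor_columns(schema, factor)
  keep <- setdiff(schema$factors, factor)
  if (length(keep) == 0) stop("cannot drop the last remaining factor")
  new_schema <- feature_schema(keep, window = schema$window,
                               alphabet = schema$alphabet,
                               pssm_scaling = schema$pssm_scaling,
                               property_scaling = schema$property_scaling)
  X <- dataset$X[, -cols, drop = FALSE]
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = dataset$y, groups = dataset$groups,
                 schema = new_schema),
            class = "windowed_dataset")
}

# internal: subset a windowed dataset by row index
subset_dataset <- function(dataset, rows) {
  structure(list(X = dataset$X[rows, , drop = FALSE],
                 y = if (is.null(dataset$y)) NULL else dataset$y[rows],
                 groups = dataset$groups[rows],
                 schema = dataset$schema),
            class = "windowed_dataset")
}

#' Split a windowed dataset by sequence
#'
#' Grouped train/test split: whole sequences are assigned to one side so
#' no residue of a protein appears in both splits (intra-protein
#' correlation would otherwise leak across the split).
#'
#' @param dataset A `windowed_dataset`.
#' @param train_fraction Fraction of sequences assigned to the training
#'   split.
#' @param seed Integer seed for the assignment.
#' @return A list with `windowed_dataset` elements `train` and `test`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.7, seed = 1) {
  ids <- unique(dataset$groups)
  n_train <- max(1L, round(length(ids) * train_fraction))
  if (n_train >= length(ids)) n_train <- length(ids) - 1L
  set.seed(seed)
  train_ids <- sample(ids, n_train)
  tr <- dataset$groups %in% train_ids
  list(train = subset_dataset(dataset, which(tr)),
       test = subset_dataset(dataset, which(!tr)))
}

#' Split a corpus tibble by sequence
#'
#' @param corpus A corpus tibble with an `id` column.
#' @param train_fraction Fraction of sequences in the training split.
#' @param seed Integer seed.
#' @return A list of two corpus tibbles, `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed = 1) {
  ids <- unique(corpus$id)
  n_train <- max(1L, round(length(ids) * train_fraction))
  if (n_train >= length(ids)) n_train <- length(ids) - 1L
  set.seed(seed)
  train_ids <- sample(ids, n_train)
  alph <- attr(corpus, "alphabet")
  tr <- corpus[corpus$id %in% train_ids, ]
  te <- corpus[!(corpus$id %in% train_ids), ]
  attr(tr, "alphabet") <- alph
  attr(te, "alphabet") <- alph
  list(train = tr, test = te)
}
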