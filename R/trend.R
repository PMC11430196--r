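# Trend factors (structural propensities): the conditional frequency of
# each amino acid within each secondary-structure state, estimated from a
# labelled corpus and min-max normalized. P(a, s) = A_as / T_s where A_as
# counts residues of amino acid a observed in state s and T_s is the total
# residue count of state s.

#' Fit a trend-factor (propensity) table from a labelled corpus
#'
#' Tallies, over every aligned (residue, label) pair of the corpus, how
#' often each amino acid occurs in each secondary-structure state. The raw
#' propensity of amino acid a in state s is the conditional frequency
#' `count(a in s) / count(s)`, so each state's 20 raw values sum to 1. Raw
#' values are then min-max rescaled to \\[0, 1\\]; by default the rescaling
#' runs within each state across the 20 amino acids, so every state's
#' propensity profile spans the full unit interval.
#'
#' Fit the table on the training split only and apply it frozen to held-out
#' data: the labels it consumes are the prediction target.
#'
#' @param corpus A tibble with columns `sequence` and `labels` (aligned,
#'   as produced by [simulate_corpus()] or by joining [read_fasta()] and
#'   [read_ss_labels()] output), with the state alphabet in the
#'   `"alphabet"` attribute or given via `alphabet`.
#' @param alphabet `"three_state"` or `"eight_state"`; defaults to the
#'   corpus attribute.
#' @param normalize_over Axis of the min-max rescaling: `"amino_acids"`
#'   (default; within each state across the 20 amino acids), `"states"`
#'   (within each amino acid across states), or `"global"`.
#' @return A `trend_table` object: a list with matrices `counts`, `raw`,
#'   `normalized` (states x 20), vector `totals` (residues per state), and
#'   metadata `alphabet`, `states`, `normalization_scope`.
#' @examples
#' co <- simulate_corpus(generator_config(n_sequences = 5, seed = 1))
#' tt <- fit_trend_table(co)
#' tidy(tt)
#' @export
fit_trend_table <- function(corpus,
                            alphabet = attr(corpus, "alphabet"),
                            normalize_over = c("amino_acids", "states",
                                               "global")) {
  normalize_over <- match.arg(normalize_over)
  if (is.null(alphabet)) {
    stop("corpus carries no alphabet attribute; pass `alphabet` explicitly")
  }
  states <- ss_alphabet(alphabet)
  stopifnot(all(c("sequence", "labels") %in% names(corpus)))
  if (!all(nchar(corpus$sequence) == nchar(corpus$labels))) {
    bad <- which(nchar(corpus$sequence) != nchar(corpus$labels))[1]
    stop("sequence and labels differ in length for record ",
         if ("id" %in% names(corpus)) sQuote(corpus$id[bad]) else bad)
  }

  aa <- unlist(strsplit(paste(corpus$sequence, collapse = ""), ""))
  ss <- unlist(strsplit(paste(corpus$labels, collapse = ""), ""))
  counts <- table(factor(ss, levels = states), factor(aa, levels = aa_alphabet()))
  counts <- matrix(as.numeric(counts), nrow = length(states),
                   dimnames = list(states, aa_alphabet()))
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("no residues observed in state ",
         paste(sQuote(states[totals == 0]), collapse = ", "),
         "; cannot estimate its propensities")
  }
  raw <- counts / totals

  normalized <- switch(normalize_over,
    amino_acids = t(apply(raw, 1, minmax_rescale)),
    states      = apply(raw, 2, minmax_rescale),
    global      = matrix(minmax_rescale(raw), nrow = nrow(raw))
  )
  dimnames(normalized) <- dimnames(raw)

  structure(list(counts = counts, totals = totals, raw = raw,
                 normalized = normalized, alphabet = alphabet,
                 states = states, normalization_scope = normalize_over),
            class = "trend_table")
}

minmax_rescale <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.trend_table <- function(x, ...) {
  cat("Trend-factor table (", x$alphabet, ", min-max over ",
      x$normalization_scope, ")\n", sep = "")
  cat("Residues per state:",
      paste(sprintf("%s=%d", x$states, as.integer(x$totals)), collapse = " "),
      "\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' Tidy a trend-factor table
#'
#' @param x A `trend_table`.
#' @param ... Unused.
#' @return A tibble with one row per (state, amino acid): `state`, `aa`,
#'   `count`, `raw`, `normalized`.
#' @export
tidy.trend_table <- function(x, ...) {
  # matrices are states x 20; as.vector() walks them column-major
  tibble::tibble(
    state = rep(x$states, times = 20),
    aa = rep(aa_alphabet(), each = length(x$states)),
    count = as.vector(x$counts),
    raw = as.vector(x$raw),
    normalized = as.vector(x$normalized)
  )
}

#' Encode a sequence with fitted trend factors
#'
#' Row i of the result holds, for each state, the normalized propensity of
#' residue i for that state — a `|states|`-wide per-residue factor.
#'
#' @param sequence An amino-acid sequence string.
#' @param trend A fitted [fit_trend_table()] object.
#' @return An `n x |states|` matrix with columns named by the states.
#' @examples
#' co <- simulate_corpus(generator_config(n_sequences = 5, seed = 1))
#' tt <- fit_trend_table(co)
#' trend_encode("AEG", tt)[, 1:3]
#' @export
trend_encode <- function(sequence, trend) {
  if (!inherits(trend, "trend_table")) {
    stop("`trend` must be a fitted trend_table (see fit_trend_table())")
  }
  ch <- seq_chars(sequence)
  idx <- match(ch, aa_alphabet())
  if (anyNA(idx)) {
    stop("residue '", ch[which(is.na(idx))[1]], "' is not a standard amino acid")
  }
  m <- t(trend$normalized[, idx, drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Serialize / restore a trend table
#'
#' `write_trend_table()` writes a CSV (rows = amino acids; per-state
#' `count_*`, `raw_*` and `norm_*` columns) plus a JSON sidecar
#' (`<path>.json`) recording the alphabet and normalization scope.
#' `read_trend_table()` reconstructs the `trend_table` object.
#'
#' @param trend A `trend_table`.
#' @param path CSV output path.
#' @return `write_trend_table()` returns `path` invisibly;
#'   `read_trend_table()` returns a `trend_table`.
#' @export
write_trend_table <- function(trend, path) {
  df <- data.frame(aa = aa_alphabet(), check.names = FALSE)
  for (s in trend$states) {
    df[[paste0("count_", s)]] <- trend$counts[s, ]
    df[[paste0("raw_", s)]] <- trend$raw[s, ]
    df[[paste0("norm_", s)]] <- trend$normalized[s, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(alphabet = trend$alphabet,
         normalization_scope = trend$normalization_scope,
         totals = as.list(trend$totals)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trend_table
#' @export
read_trend_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  states <- ss_alphabet(meta$alphabet)
  grab <- function(prefix) {
    m <- t(as.matrix(df[paste0(prefix, "_", states)]))
    dimnames(m) <- list(states, df$aa)
    m[, aa_alphabet(), drop = FALSE]
  }
  counts <- grab("count")
  structure(list(counts = counts, totals = rowSums(counts),
                 raw = grab("raw"), normalized = grab("norm"),
                 alphabet = meta$alphabet, states = states,
                 normalization_scope = meta$normalization_scope),
            class = "trend_table")
}
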