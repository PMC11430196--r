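# Prediction quality scores: residue-level Q accuracy (Q3/Q8) and the
# segment-overlap score Sov. Sov compares maximal same-state runs
# (segments) of the observed and predicted label strings: each observed
# segment that overlaps a predicted segment of the same state contributes
# (minov + sigma) / maxov weighted by its length, where minov is the
# intersection length, maxov the extent of the union, and sigma a
# boundary-tolerance allowance; unmatched observed segments contribute 0.

collapse_labels <- function(x) {
  if (length(x) == 1 && nchar(x[1]) <= 1) return(x)
  if (all(nchar(x) == 1)) paste(x, collapse = "") else x
}

#' Residue-level Q accuracy
#'
#' The percentage of residues whose predicted state matches the observed
#' state: `100 * matches / N`. Called Q3 over the three-state alphabet and
#' Q8 over the eight-state alphabet.
#'
#' @param observed,predicted Label strings (one or more sequences) or
#'   per-residue label character vectors; total lengths must match.
#' @return A percentage in \\[0, 100\\].
#' @examples
#' q_accuracy("HHECHHEC", "HHECHHCC")  # 87.5
#' @export
q_accuracy <- function(observed, predicted) {
  o <- unlist(strsplit(collapse_labels(observed), ""))
  p <- unlist(strsplit(collapse_labels(predicted), ""))
  if (length(o) != length(p)) {
    stop("observed (", length(o), ") and predicted (", length(p),
         ") differ in residue count")
  }
  if (length(o) == 0) stop("empty label input")
  100 * sum(o == p) / length(o)
}

#' Decompose a label string into maximal same-state segments
#'
#' @param labels A label string (or per-residue character vector).
#' @return A tibble with columns `state`, `start`, `end` (1-based,
#'   inclusive) and `length`, in sequence order; the segments partition
#'   the positions.
#' @examples
#' segments_from_labels("HHEC")
#' @export
segments_from_labels <- function(labels) {
  ch <- unlist(strsplit(collapse_labels(labels), ""))
  if (length(ch) == 0) stop("empty label input")
  r <- rle(ch)
  end <- cumsum(r$lengths)
  tibble::tibble(state = r$values,
                 start = end - r$lengths + 1L,
                 end = end,
                 length = r$lengths)
}

# Per-state Sov numerators and normalizers for one sequence pair.
# norm = "length": Sov'99 length-weighted normalizer (an observed segment
# counts len(S1) once per overlapping predicted segment, plus once if it
# overlaps none). norm = "fragments": each observed segment (pair) counts
# 1 and contributes the bare overlap ratio.
sov_components <- function(observed, predicted, states,
                           norm = c("length", "fragments")) {
  norm <- match.arg(norm)
  o <- unlist(strsplit(collapse_labels(observed), ""))
  p <- unlist(strsplit(collapse_labels(predicted), ""))
  if (length(o) != length(p)) {
    stop("observed (", length(o), ") and predicted (", length(p),
         ") differ in residue count")
  }
  seg_o <- segments_from_labels(o)
  seg_p <- segments_from_labels(p)
  num <- stats::setNames(numeric(length(states)), states)
  den <- stats::setNames(numeric(length(states)), states)
  for (s in states) {
    so <- seg_o[seg_o$state == s, ]
    sp <- seg_p[seg_p$state == s, ]
    if (nrow(so) == 0) next
    for (i in seq_len(nrow(so))) {
      s1 <- so[i, ]
      overlapped <- FALSE
      for (j in seq_len(nrow(sp))) {
        s2 <- sp[j, ]
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        if (minov < 1L) next
        overlapped <- TRUE
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        sigma <- min(maxov - minov, minov,
                     s1$length %/% 2L, s2$length %/% 2L)
        ratio <- min(minov + sigma, maxov) / maxov
        if (norm == "length") {
          num[s] <- num[s] + ratio * s1$length
          den[s] <- den[s] + s1$length
        } else {
          num[s] <- num[s] + ratio
          den[s] <- den[s] + 1
        }
      }
      if (!overlapped) {
        den[s] <- den[s] + if (norm == "length") s1$length else 1
      }
    }
  }
  list(num = num, den = den)
}

#' Segment-overlap (Sov) score
#'
#' Scores how well the predicted segmentation reproduces the observed one,
#' rewarding contiguous, well-placed segments and tolerating small
#' boundary shifts. The default normalizer is the length-weighted Sov'99
#' form implied by the score's segment-length weighting;
#' `norm = "fragments"` instead averages the per-pair overlap ratios over
#' segments (a fragment-count normalizer, provided for comparison).
#'
#' Sov is not symmetric: the first argument plays the reference
#' (observed) role.
#'
#' @param observed,predicted Label strings of equal length (single
#'   sequence; for corpus-level scoring see [evaluate_ss()]).
#' @param states State alphabet to score over; defaults to the distinct
#'   observed letters in canonical order.
#' @param norm `"length"` (default) or `"fragments"`.
#' @return A list with `overall` (percentage) and `per_state` (named
#'   vector of percentages; `NaN` for states absent from `observed`).
#' @examples
#' sov("HHHHHHCC", "HHCCCCCC")$overall  # 50
#' @export
sov <- function(observed, predicted, states = NULL,
                norm = c("length", "fragments")) {
  norm <- match.arg(norm)
  if (is.null(states)) {
    present <- unique(unlist(strsplit(collapse_labels(observed), "")))
    states <- if (all(present %in% ss_alphabet("three_state"))) {
      intersect(ss_alphabet("three_state"), present)
    } else {
      intersect(ss_alphabet("eight_state"), present)
    }
    if (length(states) == 0) states <- sort(present)
  }
  comp <- sov_components(observed, predicted, states, norm)
  list(overall = 100 * sum(comp$num) / sum(comp$den),
       per_state = 100 * comp$num / comp$den)
}

#' Evaluate predicted labels against observed labels
#'
#' Corpus-level evaluation: residue accuracy (Q3 or Q8) pooled over all
#' residues, Sov aggregated over sequences, per-state Sov, and the
#' observed-by-predicted confusion matrix.
#'
#' @param observed,predicted Character vectors of per-sequence label
#'   strings, aligned element-wise (each element one sequence).
#' @param alphabet `"three_state"` or `"eight_state"`.
#' @param sov_norm Sov normalizer, see [sov()].
#' @param sov_aggregate `"per_sequence"` (default: per-sequence scores,
#'   averaged with length weights) or `"pooled"` (numerators and
#'   normalizers summed across sequences before dividing).
#' @return An `ss_evaluation` object with fields `q`, `sov_overall`,
#'   `sov_per_state`, `confusion`, `n_residues`, `alphabet`.
#' @examples
#' ev <- evaluate_ss(c("HHHHEEEE", "CCCC"), c("HHHHEECC", "CCCC"))
#' glance(ev)
#' @export
evaluate_ss <- function(observed, predicted,
                        alphabet = c("three_state", "eight_state"),
                        sov_norm = c("length", "fragments"),
                        sov_aggregate = c("per_sequence", "pooled")) {
  alphabet <- match.arg(alphabet)
  sov_norm <- match.arg(sov_norm)
  sov_aggregate <- match.arg(sov_aggregate)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in sequence count")
  }
  states <- ss_alphabet(alphabet)
  comps <- purrr::map2(observed, predicted, sov_components,
                       states = states, norm = sov_norm)
  if (sov_aggregate == "pooled") {
    num <- Reduce(`+`, purrr::map(comps, "num"))
    den <- Reduce(`+`, purrr::map(comps, "den"))
    sov_overall <- 100 * sum(num) / sum(den)
    sov_per_state <- 100 * num / den
  } else {
    n_res <- nchar(observed)
    per_overall <- vapply(comps, function(cc) {
      100 * sum(cc$num) / sum(cc$den)
    }, numeric(1))
    sov_overall <- stats::weighted.mean(per_overall, n_res, na.rm = TRUE)
    sov_per_state <- vapply(states, function(s) {
      vals <- vapply(comps, function(cc) 100 * cc$num[s] / cc$den[s],
                     numeric(1))
      w <- vapply(comps, function(cc) cc$den[s], numeric(1))
      if (sum(w) == 0) return(NaN)
      stats::weighted.mean(vals[w > 0], w[w > 0])
    }, numeric(1))
  }
  o <- unlist(strsplit(observed, ""))
  p <- unlist(strsplit(predicted, ""))
  if (length(o) != length(p)) {
    stop("observed and predicted differ in residue count")
  }
  confusion <- table(observed = factor(o, states),
                     predicted = factor(p, states))
  structure(list(q = 100 * sum(o == p) / length(o),
                 sov_overall = unname(sov_overall),
                 sov_per_state = sov_per_state,
                 confusion = unclass(confusion),
                 n_residues = length(o),
                 alphabet = alphabet,
                 sov_norm = sov_norm,
                 sov_aggregate = sov_aggregate),
            class = "ss_evaluation")
}

#' @export
print.ss_evaluation <- function(x, ...) {
  m <- length(ss_alphabet(x$alphabet))
  cat(sprintf("Q%d = %.2f%%  Sov = %.2f%%  (%d residues)\n",
              m, x$q, x$sov_overall, x$n_residues))
  cat("Per-state Sov:",
      paste(sprintf("%s=%.1f", names(x$sov_per_state), x$sov_per_state),
            collapse = "  "), "\n")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ss_evaluation`.
#' @param ... Unused.
#' @return A tibble with one row per state: `state`, `sov`, `n_observed`,
#'   `recall` (per-state residue recall from the confusion matrix).
#' @export
tidy.ss_evaluation <- function(x, ...) {
  states <- ss_alphabet(x$alphabet)
  n_obs <- rowSums(x$confusion)
  tibble::tibble(
    state = states,
    sov = unname(x$sov_per_state[states]),
    n_observed = unname(n_obs[states]),
    recall = unname(ifelse(n_obs > 0, 100 * diag(x$confusion) / n_obs, NaN))
  )
}

#' @export
glance.ss_evaluation <- function(x, ...) {
  tibble::tibble(q = x$q, sov = x$sov_overall, n_residues = x$n_residues,
                 alphabet = x$alphabet)
}

# internal: regroup a per-residue prediction vector into per-sequence
# label strings following the dataset's group order
regroup_predictions <- function(pred, groups) {
  f <- factor(groups, levels = unique(groups))
  vapply(split(pred, f), paste, character(1), collapse = "")
}

#' Per-sequence label strings from a windowed dataset
#'
#' @param dataset A `windowed_dataset` with labels.
#' @param pred Optional per-residue predicted labels (defaults to the
#'   dataset's own labels).
#' @return A tibble with columns `id` and `labels`.
#' @export
dataset_labels <- function(dataset, pred = NULL) {
  if (is.null(pred)) pred <- dataset$y
  lab <- regroup_predictions(pred, dataset$groups)
  tibble::tibble(id = names(lab), labels = unname(lab))
}
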