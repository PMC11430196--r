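# Independent amino-acid propensity scoring: a training-free predictor
# that assigns each residue the state with the highest fitted propensity,
# and summarizes a whole sequence by accumulating per-residue propensity
# scores per state (the "total sequence score"). Used as a quick
# screening predictor, e.g. on the chains of protein complexes.

#' Propensity-score a sequence with a fitted trend table
#'
#' Looks up each residue's normalized propensity vector, optionally
#' smooths it with a centred running mean over `window` residues (partial
#' windows at the termini), and labels each residue with the
#' highest-propensity state. Ties go to the earlier state in the alphabet
#' order (H before E before C). Per-state totals accumulate the raw
#' (unsmoothed) per-residue propensities, so the total score of a
#' concatenation is the sum of its parts.
#'
#' @param sequence An amino-acid sequence string.
#' @param trend A fitted [fit_trend_table()].
#' @param window Odd positive smoothing window (residues); 1 disables
#'   smoothing.
#' @return A list with `totals` (named per-state sums), `labels`
#'   (predicted label string), `scores` (n x states propensity matrix)
#'   and `smoothed` (the windowed scores the labels are taken from).
#' @examples
#' co <- simulate_corpus(generator_config(n_sequences = 10, seed = 6))
#' tt <- fit_trend_table(co)
#' propensity_score_sequence("AAEEGGPP", tt)$labels
#' @export
propensity_score_sequence <- function(sequence, trend, window = 1) {
  if (!inherits(trend, "trend_table")) {
    stop("`trend` must be a fitted trend_table (see fit_trend_table())")
  }
  if (length(window) != 1 || window < 1 || window %% 2 != 1) {
    stop("`window` must be an odd positive integer")
  }
  scores <- trend_encode(sequence, trend)
  colnames(scores) <- trend$states
  smoothed <- scores
  if (window > 1) {
    w <- (window - 1) / 2
    n <- nrow(scores)
    cs <- rbind(0, apply(scores, 2, cumsum))
    lo <- pmax(seq_len(n) - w, 1L)
    hi <- pmin(seq_len(n) + w, n)
    smoothed <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  idx <- max.col(smoothed, ties.method = "first")
  list(totals = colSums(scores),
       labels = paste(trend$states[idx], collapse = ""),
       scores = scores,
       smoothed = smoothed)
}
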