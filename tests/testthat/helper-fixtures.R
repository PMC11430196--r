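# Shared in-code fixtures: everything is generated at test time from
# fixed seeds; nothing is read from disk unless a test writes it first.

# small default-structure corpus (8 sequences, ~40 residues each)
tiny_corpus <- function(seed = 101, n = 8, len = c(30, 50),
                        alphabet = "three_state") {
  simulate_corpus(generator_config(n_sequences = n, length_range = len,
                                   alphabet = alphabet, seed = seed))
}

# mid-size corpus for model tests (keeps fits fast at window 5)
model_corpus <- function(seed = 202, n = 30, len = c(40, 80)) {
  simulate_corpus(generator_config(n_sequences = n, length_range = len,
                                   seed = seed))
}

random_label_string <- function(n, states = c("H", "E", "C")) {
  paste(sample(states, n, replace = TRUE), collapse = "")
}

# Independent brute-force Sov reference: explicit position sets and
# nested loops, no shared code with the package implementation.
sov_reference <- function(observed, predicted, states = c("H", "E", "C"),
                          per_state = FALSE) {
  o <- strsplit(observed, "")[[1]]
  p <- strsplit(predicted, "")[[1]]
  stopifnot(length(o) == length(p))
  runs <- function(v, s) {
    out <- list()
    i <- 1
    while (i <= length(v)) {
      if (v[i] == s) {
        j <- i
        while (j < length(v) && v[j + 1] == s) j <- j + 1
        out[[length(out) + 1]] <- i:j
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  num_total <- 0
  den_total <- 0
  per <- stats::setNames(numeric(length(states)), states)
  per_den <- stats::setNames(numeric(length(states)), states)
  for (s in states) {
    for (seg_o in runs(o, s)) {
      hit <- FALSE
      for (seg_p in runs(p, s)) {
        ov <- intersect(seg_o, seg_p)
        if (length(ov) == 0) next
        hit <- TRUE
        minov <- length(ov)
        maxov <- length(union(seg_o, seg_p))  # both runs are contiguous
        maxov <- max(c(seg_o, seg_p)) - min(c(seg_o, seg_p)) + 1
        sigma <- min(maxov - minov, minov,
                     floor(length(seg_o) / 2), floor(length(seg_p) / 2))
        contrib <- (min(minov + sigma, maxov) / maxov) * length(seg_o)
        num_total <- num_total + contrib
        den_total <- den_total + length(seg_o)
        per[s] <- per[s] + contrib
        per_den[s] <- per_den[s] + length(seg_o)
      }
      if (!hit) {
        den_total <- den_total + length(seg_o)
        per_den[s] <- per_den[s] + length(seg_o)
      }
    }
  }
  if (per_state) return(100 * per / per_den)
  100 * sum(per) / sum(per_den)
}
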