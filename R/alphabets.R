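# Canonical alphabets. All 20-wide feature vectors use the alphabetical
# one-letter ordering; PSSM file column order is re-mapped on read.

#' Canonical amino-acid and secondary-structure alphabets
#'
#' `aa_alphabet()` returns the 20 standard amino-acid one-letter codes in
#' the canonical (alphabetical) order used for every 20-wide feature block.
#' `ss_alphabet()` returns the secondary-structure state alphabet:
#' `"three_state"` is H (helix), E (strand), C (coil); `"eight_state"` is
#' the DSSP alphabet H, G, I, E, B, T, S, C.
#'
#' @param alphabet `"three_state"` or `"eight_state"`.
#' @return A character vector of single-letter codes.
#' @examples
#' aa_alphabet()
#' ss_alphabet("eight_state")
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
ss_alphabet <- function(alphabet = c("three_state", "eight_state")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "three_state") c("H", "E", "C")
  else c("H", "G", "I", "E", "B", "T", "S", "C")
}

# internal: split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# internal: TRUE if every character of x is in `letters_ok`
all_in_alphabet <- function(x, letters_ok) {
  all(seq_chars(x) %in% letters_ok)
}

# internal: positions (1-based) of characters outside the alphabet
invalid_positions <- function(x, letters_ok) {
  which(!(seq_chars(x) %in% letters_ok))
}

#' Reduce eight-state labels to three states
#'
#' Collapses DSSP eight-state labels to the three-state alphabet using the
#' common convention H, G, I -> H; E, B -> E; T, S, C -> C. The reduction
#' rule is configurable through `mapping`, a named character vector from
#' eight-state letters to three-state letters.
#'
#' @param labels A tibble with columns `id` and `labels` (as returned by
#'   [read_ss_labels()]), or a character vector of label strings. Must be
#'   eight-state; three-state input is returned unchanged with a warning.
#' @param mapping Named character vector mapping each eight-state letter to a
#'   three-state letter. The default is the standard DSSP reduction.
#' @return The same shape as the input, with labels in the three-state
#'   alphabet and (for tibble input) the `alphabet` attribute updated.
#' @examples
#' map_8to3(c("GHIT", "EB", "SSTT"))
#' @export
map_8to3 <- function(labels,
                     mapping = c(H = "H", G = "H", I = "H",
                                 E = "E", B = "E",
                                 T = "C", S = "C", C = "C")) {
  stopifnot(setequal(names(mapping), ss_alphabet("eight_state")),
            all(mapping %in% ss_alphabet("three_state")))
  if (is.data.frame(labels)) {
    alph <- attr(labels, "alphabet")
    if (identical(alph, "three_state")) {
      warning("labels are already three-state; returning input unchanged")
      return(labels)
    }
    out <- labels
    out$labels <- vapply(labels$labels, map_string_8to3, character(1),
                         mapping = mapping, USE.NAMES = FALSE)
    attr(out, "alphabet") <- "three_state"
    return(out)
  }
  if (all(vapply(labels, all_in_alphabet, logical(1),
                 letters_ok = ss_alphabet("three_state"))) &&
      !all(nchar(labels) == 0)) {
    # heuristic only fires when no eight-state-only letter is present
    if (!any(grepl("[GIBTS]", labels))) {
      warning("labels are already three-state; returning input unchanged")
      return(labels)
    }
  }
  vapply(labels, map_string_8to3, character(1), mapping = mapping,
         USE.NAMES = FALSE)
}

map_string_8to3 <- function(x, mapping) {
  ch <- seq_chars(x)
  bad <- which(!(ch %in% names(mapping)))
  if (length(bad) > 0) {
    stop("label character '", ch[bad[1]], "' at position ", bad[1],
         " is not an eight-state letter")
  }
  paste(mapping[ch], collapse = "")
}
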