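# Physicochemical property scales for the 20 standard amino acids:
# hydrophobicity (H), NH3+ dissociation constant (pKb2), isoelectric
# point (pI) and COOH dissociation constant (pKa1). Shipped as a fixed
# reference table (AAindex-derived scale values); users may substitute
# their own table with the same shape.

#' Amino-acid property table
#'
#' Returns the shipped 20 x 4 physicochemical property table used by
#' [property_encode()]: hydrophobicity (`H`), the dissociation constant of
#' the alpha-amino group (`pKb2`), the isoelectric point (`pI`) and the
#' dissociation constant of the alpha-carboxyl group (`pKa1`). Together the
#' three dissociation-related columns track the charge state of a residue,
#' and `H` its hydrophobicity — the properties most directly implicated in
#' helix/strand/coil preference.
#'
#' @return A tibble with columns `aa`, `H`, `pKb2`, `pI`, `pKa1`, one row
#'   per amino acid in [aa_alphabet()] order.
#' @examples
#' aa_property_table()
#' @export
aa_property_table <- function() {
  tb <- tibble::tribble(
    ~aa,    ~H,  ~pKb2,   ~pI, ~pKa1,
    "R", 10.76,   2.17,  9.04, -2.53,
    "K",  9.74,   2.18,  8.95, -1.5,
    "H",  7.59,   1.82,  9.17, -0.4,
    "P",  6.3,    1.99, 10.6,   0.12,
    "A",  6,      2.34,  9.69,  0.62,
    "L",  5.98,   2.36,  9.6,   1.06,
    "I",  5.97,   2.36,  9.6,   1.38,
    "V",  5.96,   2.32,  9.62,  1.08,
    "W",  5.89,   2.83,  9.39,  0.81,
    "G",  5.79,   2.34,  9.6,   0.48,
    "M",  5.74,   2.28,  9.21,  0.64,
    "S",  5.68,   2.21,  9.15, -0.18,
    "Y",  5.66,   2.2,   9.11,  0.26,
    "Q",  5.65,   2.17,  9.13, -0.85,
    "T",  5.6,    2.09,  9.1,  -0.05,
    "F",  5.48,   1.83,  9.13,  1.19,
    "N",  5.41,   2.02,  8.8,  -0.78,
    "C",  5.07,   1.96, 10.28,  0.29,
    "E",  4.25,   2.19,  9.67, -0.74,
    "D",  3.65,   1.88,  9.6,  -0.9
  )
  tb[match(aa_alphabet(), tb$aa), ]
}

#' Encode a sequence as per-residue physicochemical properties
#'
#' Row i of the result is the property-table row for residue i, in column
#' order (H, pKb2, pI, pKa1). Optionally z-scores each column with supplied
#' statistics (typically fitted on a training split; see
#' [fit_property_scaling()]) so that property features share scale with the
#' other, \\[0, 1\\]-ranged factors used by distance-sensitive learners.
#'
#' @param sequence An amino-acid sequence string (or a tibble row's
#'   `sequence` element).
#' @param table A property table as returned by [aa_property_table()].
#' @param scaling Optional list with numeric vectors `center` and `scale`
#'   (length 4, named by the property columns); when supplied each column
#'   is transformed to `(x - center) / scale`.
#' @return An `n x 4` numeric matrix with columns `H`, `pKb2`, `pI`, `pKa1`.
#' @examples
#' property_encode("RDG")
#' @export
property_encode <- function(sequence, table = aa_property_table(),
                            scaling = NULL) {
  ch <- seq_chars(sequence)
  idx <- match(ch, table$aa)
  if (anyNA(idx)) {
    stop("residue '", ch[which(is.na(idx))[1]], "' absent from property table")
  }
  m <- as.matrix(table[idx, c("H", "pKb2", "pI", "pKa1")])
  rownames(m) <- NULL
  if (!is.null(scaling)) {
    m <- sweep(sweep(m, 2, scaling$center[colnames(m)], "-"),
               2, scaling$scale[colnames(m)], "/")
  }
  m
}

#' Fit per-column z-score statistics for the property factor
#'
#' Computes the mean and standard deviation of each property column over
#' every residue of a training corpus, for use as the `scaling` argument of
#' [property_encode()]. Fitting on the training split and freezing for test
#' data keeps the encoding free of test-set influence.
#'
#' @param corpus A corpus tibble with a `sequence` column (see
#'   [simulate_corpus()]).
#' @param table Property table, as in [property_encode()].
#' @return A list with elements `center` and `scale` (named length-4
#'   numeric vectors).
#' @export
fit_property_scaling <- function(corpus, table = aa_property_table()) {
  ch <- unlist(strsplit(paste(corpus$sequence, collapse = ""), ""))
  m <- as.matrix(table[match(ch, table$aa), c("H", "pKb2", "pI", "pKa1")])
  sds <- apply(m, 2, stats::sd)
  sds[sds == 0] <- 1
  list(center = colMeans(m), scale = sds)
}

# data-independent [0, 1] rescaling by the property table's own ranges;
# keeps property columns on the same scale as the other factor blocks
minmax_property_scaling <- function(table = aa_property_table()) {
  m <- as.matrix(table[, c("H", "pKb2", "pI", "pKa1")])
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  list(center = lo, scale = hi - lo)
}
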