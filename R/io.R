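# Readers and writers for the three on-disk formats the analysis consumes:
# FASTA sequences, FASTA-like per-residue label files, and PSI-BLAST ASCII
# PSSM files (the `-out_ascii_pssm` dialect). Plain or gzip-compressed
# files are accepted everywhere (R connections auto-detect gzip).

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file into a tibble with one row per
#' record. Sequences are upper-cased and validated against the 20-letter
#' amino-acid alphabet; records containing non-standard residues (e.g. `X`,
#' `B`, `Z`) are dropped with a message when `strict = FALSE` (mirroring the
#' usual corpus-cleaning step of removing entries with unnatural residues)
#' or raise an error when `strict = TRUE`. Dropped records are recorded in
#' the `"excluded"` attribute of the result.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @param strict If `TRUE`, any record with a letter outside the standard
#'   alphabet is an error; if `FALSE` (default) such records are excluded
#'   and reported.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`, in file order. Attribute `"excluded"`
#'   holds a tibble of dropped records (`id`, `reason`).
#' @seealso [read_ss_labels()], [read_pssm_ascii()], [write_fasta()]
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDE", ">p2", "GGKL"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, strict = FALSE) {
  recs <- read_fasta_like(path)
  recs$sequence <- toupper(recs$sequence)
  ok <- vapply(recs$sequence, all_in_alphabet, logical(1),
               letters_ok = aa_alphabet())
  excluded <- tibble::tibble(id = character(0), reason = character(0))
  if (any(!ok)) {
    bad <- recs[!ok, ]
    reasons <- vapply(seq_len(nrow(bad)), function(i) {
      pos <- invalid_positions(bad$sequence[i], aa_alphabet())[1]
      ch <- seq_chars(bad$sequence[i])[pos]
      sprintf("non-standard residue '%s' at position %d", ch, pos)
    }, character(1))
    if (strict) {
      stop("record '", bad$id[1], "': ", reasons[1])
    }
    excluded <- tibble::tibble(id = bad$id, reason = reasons)
    message("read_fasta: excluded ", nrow(bad), " record(s) with ",
            "non-standard residues: ", paste(bad$id, collapse = ", "))
  }
  out <- recs[ok, ]
  if (any(nchar(out$sequence) == 0)) {
    stop("empty sequence for record '", out$id[nchar(out$sequence) == 0][1], "'")
  }
  attr(out, "excluded") <- excluded
  out
}

# shared FASTA-like reader: returns tibble(id, sequence) without validation
read_fasta_like <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1)
  if (any(ids == "")) {
    stop("malformed header: record ", which(ids == "")[1], " has an empty id")
  }
  tibble::tibble(id = unname(ids), sequence = unname(as.character(set)))
}

#' Write sequences or label strings to a FASTA(-like) file
#'
#' @param x A tibble with columns `id` and either `sequence` or `labels`.
#' @param path Output path (a `.gz` suffix writes gzip-compressed text).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  col <- if ("sequence" %in% names(x)) "sequence" else "labels"
  set <- Biostrings::BStringSet(stats::setNames(x[[col]], x$id))
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read per-residue secondary-structure labels
#'
#' Reads a FASTA-like file whose "sequences" are per-residue structure
#' label strings, and validates every character against the declared state
#' alphabet.
#'
#' @param path Path to a FASTA-like label file (plain or `.gz`).
#' @param alphabet `"three_state"` (H/E/C) or `"eight_state"` (DSSP
#'   H/G/I/E/B/T/S/C).
#' @return A tibble with columns `id` and `labels`, with the declared
#'   alphabet stored in the `"alphabet"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "HHEC"), tf)
#' read_ss_labels(tf, "three_state")
#' @export
read_ss_labels <- function(path, alphabet = c("three_state", "eight_state")) {
  alphabet <- match.arg(alphabet)
  recs <- read_fasta_like(path)
  names(recs)[names(recs) == "sequence"] <- "labels"
  states <- ss_alphabet(alphabet)
  for (i in seq_len(nrow(recs))) {
    bad <- invalid_positions(recs$labels[i], states)
    if (length(bad) > 0) {
      stop("record '", recs$id[i], "': label '",
           seq_chars(recs$labels[i])[bad[1]], "' at position ", bad[1],
           " is not in the ", alphabet, " alphabet")
    }
  }
  attr(recs, "alphabet") <- alphabet
  recs
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the standard `-out_ascii_pssm` layout: header lines, a column
#' header naming the 20 amino acids, one row per residue with the position
#' index, the residue letter and (at least) 20 integer log-odds scores, and
#' trailing statistics lines (ignored). Only the first 20 score columns are
#' consumed. Columns are re-ordered from the file's header order to the
#' canonical alphabetical order of [aa_alphabet()].
#'
#' @param path Path to a PSSM file (plain or `.gz`).
#' @param sequence Optional amino-acid sequence to cross-check against the
#'   file's residue column; a mismatch in length or letters is an error.
#' @param id Record identifier to attach; defaults to the file's base name
#'   without extension.
#' @return An `n x 20` numeric matrix with columns named by [aa_alphabet()]
#'   and attributes `id` and `residues` (the file's residue column, as a
#'   single string).
#' @examples
#' co <- simulate_corpus(generator_config(n_sequences = 1,
#'                                        length_range = c(5, 5), seed = 1))
#' tf <- tempfile(fileext = ".pssm")
#' write_pssm_ascii(co$pssm[[1]], tf)
#' m <- read_pssm_ascii(tf, sequence = co$sequence[1])
#' dim(m)
#' @export
read_pssm_ascii <- function(path, sequence = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  header_idx <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) >= 20 && all(tok %in% aa_alphabet()) &&
        all(nchar(tok) == 1)) {
      header_idx <- i
      col_order <- tok[1:20]
      break
    }
  }
  if (is.na(header_idx)) {
    stop("no PSSM column header (20 amino-acid letters) found in ", path)
  }
  if (anyDuplicated(col_order)) {
    stop("PSSM column header repeats an amino acid in its first 20 columns; ",
         "cannot determine column order in ", path)
  }

  rows <- list()
  residues <- character(0)
  for (i in seq((header_idx + 1), length(lines))) {
    if (i > length(lines)) break
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) == 0 || tok[1] == "") break
    if (is.na(suppressWarnings(as.integer(tok[1])))) break  # trailing stats
    if (length(tok) < 22 || !(tok[2] %in% LETTERS)) {
      stop("malformed PSSM data row at line ", i, " of ", path)
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      stop("non-numeric PSSM cell at line ", i, " of ", path)
    }
    rows[[length(rows) + 1]] <- vals
    residues <- c(residues, tok[2])
  }
  if (length(rows) == 0) stop("PSSM file ", path, " contains no data rows")

  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, aa_alphabet(), drop = FALSE]

  if (!is.null(sequence)) {
    if (nchar(sequence) != nrow(scores)) {
      stop("PSSM has ", nrow(scores), " rows but sequence '", id,
           "' has ", nchar(sequence), " residues")
    }
    if (paste(residues, collapse = "") != sequence) {
      stop("PSSM residue column does not match the sequence for '", id, "'")
    }
  }
  structure(scores, id = id, residues = paste(residues, collapse = ""))
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Writes the matrix in the standard PSI-BLAST ASCII layout (header, column
#' letters in PSI-BLAST order, one indexed row per residue, trailing K and
#' Lambda lines), so that files produced here exercise the same code path
#' as real `psiblast -out_ascii_pssm` output.
#'
#' @param scores An `n x 20` matrix with columns in [aa_alphabet()] order,
#'   optionally carrying a `residues` attribute (defaults to `X`... when
#'   absent a `residues` argument is required).
#' @param path Output path.
#' @param residues The residue column to write (single string of length
#'   `n`); defaults to the matrix's `residues` attribute.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(scores, path, residues = attr(scores, "residues")) {
  stopifnot(ncol(scores) == 20)
  if (is.null(residues)) stop("residues must be supplied to write a PSSM")
  res <- seq_chars(residues)
  stopifnot(length(res) == nrow(scores))
  # PSI-BLAST writes its own fixed column order, not alphabetical
  pb_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- scores[, pb_order, drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weight ratios computed, pseudocounts used",
               paste0("          ", paste(sprintf("%4s", pb_order), collapse = ""))),
             con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%4d", round(m[i, ])), collapse = "")),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1357     0.3176"), con)
  invisible(path)
}
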