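test_that("one-hot rows are unit indicator vectors at the canonical index", {
  m <- onehot_encode("A")
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "A"]), 1)
  m2 <- onehot_encode("AA")
  expect_equal(m2[1, ], m2[2, ])
  set.seed(1)
  s <- paste(sample(aa_alphabet(), 50, replace = TRUE), collapse = "")
  expect_equal(unname(rowSums(onehot_encode(s))), rep(1, 50))
  expect_error(onehot_encode("AX"), "not a standard amino acid")
})

test_that("property encoding reproduces the reference table rows", {
  expect_equal(property_encode("R")[1, ],
               c(H = 10.76, pKb2 = 2.17, pI = 9.04, pKa1 = -2.53))
  expect_equal(property_encode("D")[1, ],
               c(H = 3.65, pKb2 = 1.88, pI = 9.6, pKa1 = -0.9))
  expect_equal(property_encode("G")[1, ],
               c(H = 5.79, pKb2 = 2.34, pI = 9.6, pKa1 = 0.48))
  # full alphabet: one row per residue, matching the table bit-for-bit
  tab <- aa_property_table()
  m <- property_encode(paste(tab$aa, collapse = ""))
  expect_equal(unname(m), unname(as.matrix(tab[, c("H", "pKb2", "pI", "pKa1")])))
  expect_error(property_encode("Z"), "absent")
})

test_that("property scaling options map the table into comparable ranges", {
  sc <- minmax_property_scaling <- ssfactors:::minmax_property_scaling()
  m <- property_encode(paste(aa_alphabet(), collapse = ""), scaling = sc)
  expect_equal(max(m), 1)
  expect_equal(min(m), 0)
  co <- tiny_corpus()
  z <- fit_property_scaling(co)
  mz <- property_encode(co$sequence[1], scaling = z)
  expect_true(all(abs(mz) < 10))
})

test_that("trend-factor estimation matches an independent double-loop tally", {
  co <- tiny_corpus(seed = 55)
  tt <- fit_trend_table(co)
  # brute force: loop over every residue of every sequence
  counts <- matrix(0, 3, 20, dimnames = list(c("H", "E", "C"), aa_alphabet()))
  for (i in seq_len(nrow(co))) {
    aa <- strsplit(co$sequence[i], "")[[1]]
    ss <- strsplit(co$labels[i], "")[[1]]
    for (j in seq_along(aa)) counts[ss[j], aa[j]] <- counts[ss[j], aa[j]] + 1
  }
  expect_equal(tt$counts, counts)
  expect_equal(tt$raw, counts / rowSums(counts))
})

test_that("raw propensities are conditional frequencies summing to one", {
  co <- tiny_corpus(seed = 56)
  tt <- fit_trend_table(co)
  expect_equal(unname(rowSums(tt$raw)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(tt$raw >= 0 & tt$raw <= 1))
})

test_that("min-max normalization spans [0, 1] along the chosen axis", {
  co <- tiny_corpus(seed = 57)
  tt <- fit_trend_table(co)  # default: within each state across amino acids
  expect_equal(unname(apply(tt$normalized, 1, max)), rep(1, 3))
  expect_equal(unname(apply(tt$normalized, 1, min)), rep(0, 3))
  tt2 <- fit_trend_table(co, normalize_over = "states")
  expect_equal(unname(apply(tt2$normalized, 2, max)), rep(1, 20))
})

test_that("a state absent from the corpus is a named error", {
  co <- tiny_corpus(seed = 58)
  co$labels <- gsub("E", "H", co$labels)
  expect_error(fit_trend_table(co), "'E'")
})

test_that("fit_trend_table is invariant to sequence order", {
  co <- tiny_corpus(seed = 59)
  perm <- co[rev(seq_len(nrow(co))), ]
  attr(perm, "alphabet") <- "three_state"
  expect_equal(fit_trend_table(co)[c("counts", "raw", "normalized")],
               fit_trend_table(perm)[c("counts", "raw", "normalized")])
})

test_that("trend encoding is a per-residue lookup of normalized scores", {
  co <- tiny_corpus(seed = 60)
  tt <- fit_trend_table(co)
  m <- trend_encode("AAG", tt)
  expect_equal(m[1, ], m[2, ])
  expect_equal(unname(m[3, ]), unname(tt$normalized[, "G"]))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(trend_encode("AAG", list()), "trend_table")
})

test_that("trend tables serialize losslessly to CSV + JSON sidecar", {
  co <- tiny_corpus(seed = 61)
  tt <- fit_trend_table(co)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trend_table(tt, tf)
  back <- read_trend_table(tf)
  expect_equal(back$raw, tt$raw)
  expect_equal(back$normalized, tt$normalized)
  expect_equal(back$counts, tt$counts)
  expect_equal(back$normalization_scope, tt$normalization_scope)
})

test_that("PSSM scaling is the logistic map by default, identity on request", {
  m20 <- matrix(0, 2, 20)
  expect_equal(pssm_encode(m20)[1, 1], 0.5)
  expect_equal(pssm_encode(m20, "none"), m20)
  sig <- pssm_encode(matrix(seq(-9.5, 9.5, by = 1), nrow = 1))
  expect_true(all(diff(sig[1, ]) > 0))  # monotone in the raw score
})

test_that("window construction pads termini with zero and keeps width", {
  f <- matrix(c(5, 7), ncol = 1)
  w <- build_windows(f, 3)
  expect_equal(w, rbind(c(0, 5, 7), c(5, 7, 0)))
  expect_equal(build_windows(f, 1), f, ignore_attr = TRUE)
  set.seed(2)
  f2 <- matrix(rnorm(12 * 4), 12, 4)
  expect_equal(dim(build_windows(f2, 5)), c(12, 20))
  # centre block of the window equals the original features
  expect_equal(build_windows(f2, 5)[, 9:12], f2, ignore_attr = TRUE)
  expect_error(build_windows(f2, 4), "odd")
  expect_error(build_windows(f2, -1), "odd")
})

test_that("assembled datasets concatenate factor blocks in schema order", {
  co <- tiny_corpus(seed = 62)
  sch1 <- feature_schema("onehot", window = 5)
  ds1 <- encode_corpus(fit_encoder(co, sch1), co)
  manual <- do.call(rbind, lapply(co$sequence, function(s) {
    build_windows(onehot_encode(s), 5)
  }))
  expect_equal(unname(ds1$X), unname(manual))
  expect_equal(ds1$y, unlist(strsplit(paste(co$labels, collapse = ""), "")))
  expect_equal(ds1$groups, rep(co$id, nchar(co$sequence)))
})

test_that("the full three-state schema at window 13 is 611 columns wide", {
  sch <- feature_schema(window = 13)
  expect_equal(sch$per_position_width, 47)
  expect_equal(sch$total_width, 611)
  sch8 <- feature_schema(window = 13, alphabet = "eight_state")
  expect_equal(sch8$total_width, 13 * 52)
})

test_that("factor columns are recoverable and droppable as whole blocks", {
  co <- tiny_corpus(seed = 63)
  sch <- feature_schema(window = 3)
  ds <- encode_corpus(fit_encoder(co, sch), co)
  cols <- factor_columns(sch, "properties")
  expect_length(cols, 4 * 3)
  dropped <- drop_factor(ds, "properties")
  expect_equal(ncol(dropped$X), ncol(ds$X) - length(cols))
  expect_equal(unname(dropped$X), unname(ds$X[, -cols]))
  expect_equal(dropped$schema$factors, c("onehot", "pssm", "trend"))
  expect_error(factor_columns(sch, "bogus"), "not in the schema")
})

test_that("feature assembly is deterministic", {
  co <- tiny_corpus(seed = 64)
  sch <- feature_schema(window = 3)
  enc <- fit_encoder(co, sch)
  expect_identical(encode_corpus(enc, co)$X, encode_corpus(enc, co)$X)
})

test_that("no feature column is constant under default settings", {
  co <- tiny_corpus(seed = 65, n = 12)
  ds <- encode_corpus(fit_encoder(co, feature_schema(window = 3)), co)
  ranges <- apply(ds$X, 2, function(col) diff(range(col)))
  expect_true(all(ranges > 0))
})

test_that("a schema with pssm requires PSSMs in the corpus", {
  co <- tiny_corpus(seed = 66)
  co$pssm <- NULL
  enc <- structure(list(schema = feature_schema(c("onehot", "pssm"),
                                                window = 3),
                        trend = NULL, property_scaling = NULL,
                        property_table = aa_property_table()),
                   class = "ss_encoder")
  expect_error(encode_corpus(enc, co), "pssm")
})
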