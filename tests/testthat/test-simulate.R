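test_that("identical seeds reproduce the corpus exactly", {
  cfg <- generator_config(n_sequences = 5, length_range = c(20, 40), seed = 33)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$labels, b$labels)
  expect_identical(a$pssm, b$pssm)
  c2 <- simulate_corpus(generator_config(n_sequences = 5,
                                         length_range = c(20, 40), seed = 34))
  expect_false(identical(a$sequence, c2$sequence))
})

test_that("an absorbing chain with a deterministic emission is degenerate", {
  trans <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  em <- matrix(1e-12, 3, 20)
  em[, 1] <- 1 - 19e-12  # everything emits A
  em <- em / rowSums(em)
  cfg <- generator_config(n_sequences = 3, length_range = c(10, 10),
                          transition = trans, emission = em, seed = 1)
  co <- simulate_corpus(cfg)
  expect_true(all(co$labels == strrep("H", 10)))
  expect_true(all(co$sequence == strrep("A", 10)))
})

test_that("invalid stochastic matrices are rejected", {
  bad <- matrix(0.5, 3, 3)
  expect_error(generator_config(transition = bad), "rows summing to 1")
  bad_em <- matrix(1 / 19, 3, 20)
  expect_error(generator_config(emission = bad_em), "rows summing to 1")
})

test_that("simulated PSSMs are integer profiles favouring the true residue", {
  cfg <- generator_config(n_sequences = 1, length_range = c(30, 30),
                          pssm_noise = 400, pssm_context = 0, seed = 5)
  co <- simulate_corpus(cfg)
  p <- co$pssm[[1]]
  expect_equal(dim(p), c(30, 20))
  expect_true(all(p == round(p)))
  # sharp profiles: argmax of each row is the true residue's column
  argmax <- aa_alphabet()[apply(p, 1, which.max)]
  expect_equal(paste(argmax, collapse = ""), co$sequence[1])
})

test_that("mean segment length tracks the self-transition stickiness", {
  co <- simulate_corpus(generator_config(n_sequences = 150,
                                         length_range = c(150, 250),
                                         seed = 21))
  seg <- dplyr::bind_rows(lapply(co$labels, segments_from_labels))
  mean_len <- tapply(seg$length, seg$state, mean)
  # geometric mean length 1/(1-p_self), shortened by sequence truncation;
  # defaults: H/E stickiness 0.9 (≈10), C 0.8 (≈5)
  expect_gt(mean_len["H"], 7); expect_lt(mean_len["H"], 12)
  expect_gt(mean_len["E"], 7); expect_lt(mean_len["E"], 12)
  expect_gt(mean_len["C"], 3.5); expect_lt(mean_len["C"], 6.5)
})

test_that("trend recovery approaches the generating emissions", {
  co <- simulate_corpus(generator_config(n_sequences = 300,
                                         length_range = c(150, 250),
                                         seed = 22))
  rec <- fit_recovery_check(co)
  expect_false(rec$low_n)
  expect_true(rec$all_within_bound)
  # deviation shrinks with corpus size (same seed family, 4x residues)
  co_small <- simulate_corpus(generator_config(n_sequences = 30,
                                               length_range = c(150, 250),
                                               seed = 22))
  rec_small <- fit_recovery_check(co_small)
  expect_true(rec_small$low_n)
  expect_lt(rec$max_abs_deviation, rec_small$max_abs_deviation)
})

test_that("uniform emissions recover raw propensities near 1/20", {
  em <- matrix(1 / 20, 3, 20)
  co <- simulate_corpus(generator_config(n_sequences = 80,
                                         length_range = c(150, 250),
                                         emission = em, seed = 23))
  tt <- fit_trend_table(co)
  expect_true(all(abs(tt$raw - 0.05) < 0.02))
})

test_that("eight-state simulation feeds the full eight-state pipeline", {
  co <- simulate_corpus(generator_config(n_sequences = 10,
                                         length_range = c(60, 90),
                                         alphabet = "eight_state", seed = 24))
  expect_equal(attr(co, "alphabet"), "eight_state")
  tt <- fit_trend_table(co)
  expect_equal(dim(tt$raw), c(8, 20))
  sch <- feature_schema(window = 3, alphabet = "eight_state")
  ds <- encode_corpus(fit_encoder(co, sch), co)
  expect_equal(ncol(ds$X), 3 * 52)
  expect_true(all(ds$y %in% ss_alphabet("eight_state")))
})

test_that("factor datasets have exchangeable blocks and aligned labels", {
  cfg <- generator_config(n_sequences = 6, length_range = c(20, 30), seed = 25)
  ds <- simulate_factor_dataset(cfg)
  expect_equal(ds$schema$factors, paste0("factor", 1:4))
  expect_equal(ncol(ds$X), 12)
  expect_equal(length(ds$y), nrow(ds$X))
  expect_identical(simulate_factor_dataset(cfg)$X, ds$X)
  # informative blocks carry the label signal: block mean at the true
  # label's column exceeds the others
  cols <- factor_columns(ds$schema, "factor1")
  block <- ds$X[, cols]
  idx <- match(ds$y, ss_alphabet("three_state"))
  on_signal <- mean(block[cbind(seq_len(nrow(block)), idx)])
  expect_gt(on_signal, mean(block) + 0.5)
})
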