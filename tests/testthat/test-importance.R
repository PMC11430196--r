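test_that("a perfectly predictive factor takes nearly all the share", {
  cfg <- generator_config(n_sequences = 40, length_range = c(40, 80),
                          seed = 401)
  ds <- simulate_factor_dataset(cfg, informative = c(TRUE, FALSE, FALSE, FALSE),
                                noise_sd = 0.1)
  sp <- split_dataset(ds, seed = 401)
  m <- train_ss_model(sp$train, "naive_bayes")
  imp <- grouped_importance(m, sp$test, repeats = 5, seed = 401)
  expect_gt(imp$per_factor$share[1], 90)
  # pure-noise factors: raw drop indistinguishable from zero
  expect_true(all(abs(imp$per_factor$raw_drop[-1]) < 1))
  expect_equal(sum(imp$per_factor$share), 100, tolerance = 1e-6)
})

test_that("duplicated factors share importance symmetrically", {
  cfg <- generator_config(n_sequences = 40, length_range = c(40, 80),
                          seed = 402)
  ds <- simulate_factor_dataset(cfg, informative = c(TRUE, TRUE),
                                noise_sd = 0.6,
                                factor_names = c("left", "right"))
  # make the two blocks exact duplicates
  ds$X[, factor_columns(ds$schema, "right")] <-
    ds$X[, factor_columns(ds$schema, "left")]
  sp <- split_dataset(ds, seed = 402)
  m <- train_ss_model(sp$train, "naive_bayes")
  imp <- grouped_importance(m, sp$test, repeats = 10, seed = 402)
  expect_equal(imp$per_factor$share[1], imp$per_factor$share[2],
               tolerance = 0.15)
})

test_that("shares are floored at zero and sum to 100", {
  cfg <- generator_config(n_sequences = 30, length_range = c(40, 60),
                          seed = 403)
  ds <- simulate_factor_dataset(cfg, informative = c(TRUE, TRUE, FALSE, FALSE),
                                noise_sd = 0.8)
  sp <- split_dataset(ds, seed = 403)
  m <- train_ss_model(sp$train, "naive_bayes")
  imp <- grouped_importance(m, sp$test, repeats = 5, seed = 403)
  expect_true(all(imp$per_factor$share >= 0))
  expect_equal(sum(imp$per_factor$share), 100, tolerance = 1e-6)
  expect_true(all(c("raw_drop", "floored_drop") %in% names(tidy(imp))))
})

test_that("single-factor schemas are rejected", {
  co <- tiny_corpus(seed = 404)
  sch <- feature_schema("onehot", window = 3)
  ds <- encode_corpus(fit_encoder(co, sch), co)
  m <- train_ss_model(ds, "naive_bayes")
  expect_error(grouped_importance(m, ds), "single-factor")
})

test_that("importance is reproducible under a fixed seed", {
  cfg <- generator_config(n_sequences = 20, length_range = c(30, 50),
                          seed = 405)
  ds <- simulate_factor_dataset(cfg, noise_sd = 0.8)
  sp <- split_dataset(ds, seed = 405)
  m <- train_ss_model(sp$train, "naive_bayes")
  a <- grouped_importance(m, sp$test, repeats = 4, seed = 9)
  b <- grouped_importance(m, sp$test, repeats = 4, seed = 9)
  expect_identical(a$per_factor, b$per_factor)
})
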