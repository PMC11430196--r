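# model behaviour is exercised on small factor datasets (fast, separable
# when noise_sd is small) and a small windowed corpus

sep_dataset <- function(seed = 301) {
  simulate_factor_dataset(
    generator_config(n_sequences = 6, length_range = c(15, 25), seed = seed),
    noise_sd = 0.05)
}

test_that("all four families fit separable data perfectly on-train", {
  ds <- sep_dataset()
  for (fam in c("svm", "random_forest", "knn", "naive_bayes")) {
    m <- train_ss_model(ds, fam, seed = 1)
    expect_equal(q_accuracy(ds$y, predict(m, ds$X)), 100)
  }
})

test_that("1-NN self-prediction is perfect when points are distinct", {
  ds <- sep_dataset(302)
  expect_equal(nrow(unique(as.data.frame(ds$X))), nrow(ds$X))
  m <- train_ss_model(ds, "knn", k = 1)
  expect_equal(predict(m, ds$X), ds$y)
})

test_that("fits are deterministic under equal seed, data and settings", {
  ds <- simulate_factor_dataset(
    generator_config(n_sequences = 8, length_range = c(15, 25), seed = 303),
    noise_sd = 1.2)
  for (fam in c("svm", "random_forest", "knn", "naive_bayes")) {
    m1 <- train_ss_model(ds, fam, seed = 7)
    m2 <- train_ss_model(ds, fam, seed = 7)
    expect_identical(predict(m1, ds$X), predict(m2, ds$X))
  }
})

test_that("prediction contract: width checks, empty input, label closure", {
  ds <- sep_dataset(304)
  m <- train_ss_model(ds, "naive_bayes")
  expect_error(predict(m, ds$X[, -1]), "width")
  expect_identical(predict(m, ds$X[0, , drop = FALSE]), character(0))
  expect_true(all(predict(m, ds$X) %in% ss_alphabet("three_state")))
})

test_that("degenerate training sets are rejected", {
  ds <- sep_dataset(305)
  ds$y[] <- "H"
  expect_error(train_ss_model(ds, "svm"), "single class")
  ds0 <- ssfactors:::subset_dataset(ds, integer(0))
  expect_error(train_ss_model(ds0, "svm"), "empty")
})

test_that("the SVM subsample cap is applied, seeded, and announced", {
  ds <- simulate_factor_dataset(
    generator_config(n_sequences = 20, length_range = c(60, 80), seed = 306),
    noise_sd = 1)
  expect_message(m <- train_ss_model(ds, "svm", subsample_cap = 500, seed = 2),
                 "subsampling")
  expect_equal(m$n_train, 500)
  expect_silent(train_ss_model(ds, "naive_bayes", seed = 2))
})

test_that("in-package KNN agrees with class::knn", {
  skip_if_not_installed("class")
  ds <- simulate_factor_dataset(
    generator_config(n_sequences = 10, length_range = c(20, 30), seed = 307),
    noise_sd = 0.8)
  sp <- split_dataset(ds, seed = 3)
  m <- train_ss_model(sp$train, "knn", k = 1)
  ours <- predict(m, sp$test$X)
  ref <- as.character(class::knn(sp$train$X, sp$test$X,
                                 factor(sp$train$y), k = 1))
  expect_identical(ours, ref)
})

test_that("in-package Gaussian NB agrees with e1071::naiveBayes", {
  ds <- simulate_factor_dataset(
    generator_config(n_sequences = 8, length_range = c(20, 30), seed = 308),
    noise_sd = 0.8)
  sp <- split_dataset(ds, seed = 3)
  m <- train_ss_model(sp$train, "naive_bayes")
  ours <- predict(m, sp$test$X)
  df <- as.data.frame(sp$train$X)
  ref_fit <- e1071::naiveBayes(df, factor(sp$train$y))
  ref <- as.character(predict(ref_fit, as.data.frame(sp$test$X)))
  expect_gt(mean(ours == ref), 0.995)
})

test_that("grid search ranks by held-out Q with stable ties", {
  co <- model_corpus()
  sp <- split_corpus(co, seed = 4)
  sch <- feature_schema(c("onehot", "trend"), window = 5)
  enc <- fit_encoder(sp$train, sch)
  tr <- encode_corpus(enc, sp$train)
  te <- encode_corpus(enc, sp$test)

  one <- grid_search(tr, te, "knn", grid = 3)
  expect_equal(nrow(one), 1)
  expect_true(all(one$q >= 0 & one$q <= 100))

  g <- grid_search(tr, te, "knn", grid = c(1, 3))
  expect_equal(nrow(g), 2)
  expect_true(!is.unsorted(rev(g$q)))
  expect_error(grid_search(tr, te, "knn", grid = numeric(0)), "empty")
})

test_that("an RBF kernel beats a linear kernel on these state boundaries", {
  co <- model_corpus(seed = 205)
  sp <- split_corpus(co, seed = 5)
  sch <- feature_schema(window = 5)
  enc <- fit_encoder(sp$train, sch)
  tr <- encode_corpus(enc, sp$train)
  te <- encode_corpus(enc, sp$test)
  g <- grid_search(tr, te, "svm", grid = c("Linear", "RBF"), seed = 5)
  expect_gt(g$q[g$value == "RBF"], g$q[g$value == "Linear"])
})

test_that("every family clears the majority baseline on held-out residues", {
  co <- model_corpus(seed = 206)
  sp <- split_corpus(co, seed = 6)
  enc <- fit_encoder(sp$train, feature_schema(window = 5))
  tr <- encode_corpus(enc, sp$train)
  te <- encode_corpus(enc, sp$test)
  baseline <- 100 * max(table(te$y)) / length(te$y)
  for (fam in c("svm", "random_forest", "knn", "naive_bayes")) {
    m <- train_ss_model(tr, fam, seed = 6)
    expect_gt(q_accuracy(te$y, predict(m, te$X)), baseline)
  }
})

test_that("model summaries expose the fit metadata", {
  ds <- sep_dataset(309)
  m <- train_ss_model(ds, "random_forest", seed = 9)
  g <- glance(m)
  expect_equal(g$family, "random_forest")
  expect_equal(g$n_train, nrow(ds$X))
  expect_equal(g$window, 1L)
})
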