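test_that("a zero-stage model predicts the initial constant", {
  d <- small_training_matrix(n = 30)
  fit <- gbrt_fit(d$X, d$y, n_stages = 0)
  expect_equal(predict(fit, d$X), rep(stats::median(d$y), 30))
  fit_sq <- gbrt_fit(d$X, d$y, n_stages = 0, loss = "squared")
  expect_equal(predict(fit_sq, d$X), rep(mean(d$y), 30))
})

test_that("constant targets stay constant through boosting", {
  X <- matrix(runif(40), ncol = 2)
  fit <- gbrt_fit(X, rep(0.42, 20), n_stages = 10, shrinkage = 1)
  expect_equal(predict(fit, X), rep(0.42, 20), tolerance = 1e-12)
})

test_that("staged predictions match a naive boosting reference loop", {
  set.seed(11)
  X <- matrix(runif(20), ncol = 2)
  y <- runif(10)
  fit <- gbrt_fit(X, y, n_stages = 3, shrinkage = 1, loss = "squared",
                  max_depth = 1, min_samples_leaf = 1)
  ref <- naive_stump_boost(X, y, 3)
  got <- staged_predict(fit, X, stages = 0:3, clip = FALSE)
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("an unconstrained squared-loss model drives training error to zero", {
  d <- small_training_matrix(n = 40, seed = 2)
  fit <- gbrt_fit(d$X, d$y, n_stages = 60, shrinkage = 1, loss = "squared",
                  max_depth = 12, min_samples_leaf = 1)
  expect_equal(predict(fit, d$X, clip = FALSE), d$y, tolerance = 1e-8)
})

test_that("training loss is non-increasing per stage for both losses", {
  d <- small_training_matrix(n = 150, seed = 5)
  for (loss in c("huber", "squared")) {
    fit <- gbrt_fit(d$X, d$y, n_stages = 40, shrinkage = 0.2, loss = loss,
                    max_depth = 3, min_samples_leaf = 2)
    expect_true(all(fit$train_loss$loss_after <=
                      fit$train_loss$loss_before + 1e-9))
  }
})

test_that("prediction clips to the RSA range by default", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  y <- c(-0.5, 0, 1, 1.5) # deliberately outside [0, 1]
  fit <- gbrt_fit(X, y, n_stages = 20, shrinkage = 1, loss = "squared",
                  max_depth = 2, min_samples_leaf = 1)
  p <- predict(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(any(predict(fit, X, clip = FALSE) < 0))
})

test_that("invalid inputs are rejected before training or prediction", {
  d <- small_training_matrix(n = 20)
  Xbad <- d$X; Xbad[3, 2] <- NA
  expect_error(gbrt_fit(Xbad, d$y, n_stages = 2), "non-finite")
  ybad <- d$y; ybad[1] <- Inf
  expect_error(gbrt_fit(d$X, ybad, n_stages = 2), "non-finite")
  fit <- gbrt_fit(d$X, d$y, n_stages = 2)
  expect_error(predict(fit, d$X[, 1:2]), "4 columns, got 2")
})

test_that("fitting is deterministic and serialisation is lossless", {
  d <- small_training_matrix(n = 120, seed = 9)
  fit1 <- gbrt_fit(d$X, d$y, n_stages = 25, max_depth = 3,
                   min_samples_leaf = 2)
  fit2 <- gbrt_fit(d$X, d$y, n_stages = 25, max_depth = 3,
                   min_samples_leaf = 2)
  expect_identical(fit1, fit2)
  expect_identical(predict(fit1, d$X), predict(fit2, d$X))

  path <- withr::local_tempfile(fileext = ".json")
  gbrt_to_json(fit1, path)
  back <- gbrt_from_json(path)
  expect_identical(back$f0, fit1$f0)
  expect_identical(back$deltas, fit1$deltas)
  expect_identical(predict(back, d$X), predict(fit1, d$X))
})

test_that("feature importance concentrates on the planted signal column", {
  set.seed(21)
  X <- matrix(runif(600), ncol = 3)
  y <- X[, 1] # depends on column 1 only
  fit <- gbrt_fit(X, y, n_stages = 15, shrinkage = 0.5, loss = "squared",
                  max_depth = 2, min_samples_leaf = 5,
                  column_labels = c("A.x", "B.x", "C.x"))
  imp <- feature_importance(fit)
  expect_equal(sum(imp), 1)
  expect_true(imp[1] > max(imp[-1]))
  fam <- feature_importance(fit, by_family = TRUE)
  expect_equal(unname(fam["A"]), unname(imp[1]))

  # single split: all importance on that split's feature
  one <- gbrt_fit(matrix(c(0, 1)), c(0, 1), n_stages = 1, shrinkage = 1,
                  loss = "squared", max_depth = 1, min_samples_leaf = 1)
  expect_equal(unname(feature_importance(one)), 1)

  # no splits at all: uniform zeros
  none <- gbrt_fit(matrix(c(0, 1)), c(0.5, 0.5), n_stages = 2,
                   loss = "squared", max_depth = 1, min_samples_leaf = 1)
  expect_equal(unname(feature_importance(none)), 0)
})
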