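test_that("error metrics match direct substitution into their definitions", {
  expect_equal(rsa_mae(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(rsa_mae(c(0.2, 0.4), c(0.1, 0.5)), 10.0)
  expect_equal(rsa_mae(0.3, 0.7), 40.0)
  expect_equal(rsa_rmse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(rsa_rmse(c(0.1, -0.1), c(0, 0)), 10.0)
  expect_equal(rsa_rmse(c(0, 0.2), c(0, 0)), 100 * sqrt(0.02))
  expect_error(rsa_mae(1:3 / 10, 1:2 / 10), "length")
})

test_that("PCC matches an independent two-pass computation", {
  expect_equal(rsa_pcc(c(2, 4, 6), c(1, 2, 3)), 1)
  expect_equal(rsa_pcc(-c(1, 2, 3), c(1, 2, 3)), -1)
  expect_equal(rsa_pcc(c(0.1, 0.4, 0.2, 0.8), c(0.2, 0.5, 0.1, 0.9)),
               pcc_oracle(c(0.1, 0.4, 0.2, 0.8), c(0.2, 0.5, 0.1, 0.9)),
               tolerance = 1e-12)
  expect_error(rsa_pcc(rep(0.5, 4), c(0.1, 0.2, 0.3, 0.4)), "variance")
})

test_that("PCC is invariant under positive affine maps, flips sign under negative", {
  set.seed(4)
  x <- runif(50); y <- runif(50)
  base <- rsa_pcc(x, y)
  expect_equal(rsa_pcc(2.5 * x + 0.3, y), base, tolerance = 1e-12)
  expect_equal(rsa_pcc(x, 0.1 * y - 7), base, tolerance = 1e-12)
  expect_equal(rsa_pcc(-2 * x + 1, y), -base, tolerance = 1e-12)
})

test_that("RMSE dominates MAE and both vanish only at equality", {
  set.seed(6)
  for (i in 1:25) {
    p <- runif(30); t <- runif(30)
    expect_gte(rsa_rmse(p, t), rsa_mae(p, t))
    expect_gt(rsa_mae(p, t), 0)
  }
})

test_that("MCC follows its confusion-matrix definition and conventions", {
  expect_equal(mcc_from_counts(3, 4, 1, 2), 10 / sqrt(600))
  expect_equal(mcc_from_counts(3, 4, 1, 2), 0.408, tolerance = 1e-3)
  expect_equal(mcc_from_counts(10, 0, 0, 0), 0) # degenerate denominator
  # against the phi coefficient on random confusion matrices
  set.seed(12)
  for (i in 1:200) {
    cm <- rmultinom(1, 40, c(0.3, 0.3, 0.2, 0.2))[, 1]
    phi <- phi_oracle(cm[1], cm[2], cm[3], cm[4])
    got <- mcc_from_counts(cm[1], cm[2], cm[3], cm[4])
    if (is.na(phi)) expect_equal(got, 0) else
      expect_equal(got, phi, tolerance = 1e-12)
  }
})

test_that("two-state reports count the confusion table correctly", {
  truth <- c(0.01, 0.02, 0.5, 0.9, 0.04, 0.6)
  pred <- c(0.02, 0.50, 0.6, 0.7, 0.01, 0.02)
  r <- two_state_report(pred, truth, threshold = 5)
  # exposed is the positive class
  expect_equal(r$tp, 2); expect_equal(r$tn, 2)
  expect_equal(r$fp, 1); expect_equal(r$fn, 1)
  expect_equal(r$acc, 100 * 4 / 6)
  expect_equal(r$mcc, mcc_from_counts(2, 2, 1, 1))

  perfect <- two_state_report(truth, truth, 25)
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$mcc, 1)

  same <- two_state_report(rep(0.9, 5), rep(0.8, 5), 25)
  expect_equal(same$acc, 100)
  expect_equal(same$mcc, 0) # single-class convention

  tab <- two_state_table(pred, truth)
  expect_equal(tab$threshold, c(5, 10, 20, 25, 30, 40, 50))
  expect_true(all(tab$tp + tab$tn + tab$fp + tab$fn == 6))
})

test_that("per-residue profiles partition the data and recover planted bias", {
  # single type: profile equals the global metrics
  p <- runif(10); t <- runif(10)
  prof <- per_residue_profile(p, t, rep("A", 10))
  expect_equal(nrow(prof), 1)
  expect_equal(prof$mae, rsa_mae(p, t))
  expect_equal(prof$rmse, rsa_rmse(p, t))

  # planted per-type bias is recovered and counts sum to N
  set.seed(9)
  res <- sample(c("G", "V"), 400, replace = TRUE)
  truth <- runif(400, 0.2, 0.8)
  pred <- truth + ifelse(res == "G", 0.10, 0.02)
  prof2 <- per_residue_profile(pred, truth, res)
  expect_equal(sum(prof2$n), 400)
  expect_equal(prof2$mae[prof2$residue == "G"], 10)
  expect_equal(prof2$mae[prof2$residue == "V"], 2)
  expect_equal(prof2$mean_pred - prof2$mean_true,
               ifelse(prof2$residue == "G", 0.10, 0.02))
})
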