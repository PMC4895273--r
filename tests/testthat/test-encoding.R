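test_that("logistic normalisation follows the standard logistic function", {
  expect_equal(logistic_normalize(0), 0.5)
  expect_equal(logistic_normalize(2), 1 / (1 + exp(-2)))
  expect_equal(logistic_normalize(2), 0.8808, tolerance = 1e-4)
  expect_lt(abs(logistic_normalize(50) - 1), 1e-12)
  expect_lt(logistic_normalize(-50), 1e-12)
})

test_that("encoded width matches the closed form for every window length", {
  rec <- worked_example()
  prop <- matrix(1 / 6, 20, 6, dimnames = list(rsaboost:::AA20,
                                               rsaboost:::SCE_CLASSES))
  for (L in seq(3, 17, 2)) {
    l <- (L - 1) / 2
    expect_equal(n_feature_columns(l), 26 * L + 6)
    X <- encode_protein(rec, half_width = l, propensity = prop)
    expect_equal(ncol(X), 26 * L + 6)
    expect_true(all(X >= 0 & X <= 1))
  }
  expect_equal(n_feature_columns(3, c("PSSM", "SS")), 20 * 7 + 3 * 7)
})

test_that("termini are padded with the neutral values", {
  rec <- worked_example()
  X <- encode_protein(rec, half_width = 3, families = "PSSM")
  # first residue: the 3 left window slots (60 columns) are all 0.5
  expect_equal(unname(X[1, 1:60]), rep(0.5, 60))
  # its own position (offset 0) is the normalised PSSM row
  expect_equal(unname(X[1, 61:80]),
               unname(logistic_normalize(rec$pssm[1, ])))
  Xss <- encode_protein(rec, half_width = 2, families = "SS")
  expect_equal(unname(Xss[1, 1:6]), rep(1 / 3, 6))
  Xcs <- encode_protein(rec, half_width = 1, families = "CS")
  expect_equal(unname(Xcs[1, 1]), 0.5)
})

test_that("a zero-width PSSM window is the residue's own normalised row", {
  rec <- worked_example()
  X <- encode_protein(rec, half_width = 0, families = "PSSM")
  expect_equal(ncol(X), 20)
  expect_equal(unname(X), unname(logistic_normalize(rec$pssm)))
})

test_that("encoding is position-equivariant under sequence prefixing", {
  rec <- SMALL_RECORDS[[1]]
  k <- 4L
  pre <- SMALL_RECORDS[[2]]
  shifted <- protein_record(
    id = "shifted", sequence = c(pre$sequence[1:k], rec$sequence),
    pssm = rbind(pre$pssm[1:k, ], rec$pssm),
    info = c(pre$info[1:k], rec$info),
    ss = rbind(pre$ss[1:k, ], rec$ss),
    diso = rbind(pre$diso[1:k, ], rec$diso))
  prop <- sce_propensity(SMALL_RECORDS)
  cb <- c(0, 2.3)
  l <- 3L
  X1 <- encode_protein(rec, l, propensity = prop, cs_bounds = cb)
  X2 <- encode_protein(shifted, l, propensity = prop, cs_bounds = cb)
  interior <- (l + 1):(length(rec$sequence) - l)
  expect_equal(X1[interior, ], X2[interior + k, ])
})

test_that("side-chain classes partition the (RSA, F) unit square", {
  g <- seq(0, 1, length.out = 101)
  grid <- expand.grid(rsa = g, f = g)
  cls <- side_chain_class(grid$rsa, grid$f)
  expect_false(anyNA(cls))
  expect_equal(length(cls), 101 * 101)
  ref <- mapply(sce_oracle, grid$rsa, grid$f)
  expect_equal(as.character(cls), unname(ref))
  # spec'd boundary examples
  expect_equal(as.character(side_chain_class(0.05, 0.50)), "B2")
  expect_equal(as.character(side_chain_class(0.36, 0.99)), "E")
  expect_equal(as.character(side_chain_class(0.20, 0.70)), "P2")
  expect_error(side_chain_class(1.2, 0.5), "0, 1")
})

test_that("the propensity table reflects planted class composition", {
  # a fake training set where every Ala is exposed and every Gly is B1
  rec <- protein_record(id = "T", sequence = rep(c("A", "G"), 30),
                        rsa = rep(c(0.9, 0.01), 30),
                        polar = rep(c(0.5, 0.1), 30))
  prop <- sce_propensity(list(rec))
  expect_equal(rowSums(prop), setNames(rep(1, 20), rsaboost:::AA20))
  expect_gt(prop["A", "E"], 0.8)
  expect_gt(prop["G", "B1"], 0.8)
  # unseen types fall back to the smoothed uniform
  expect_equal(unname(prop["W", ]), rep(1 / 6, 6))
  # unknown letters encode as the uniform vector
  rows <- rsaboost:::sce_rows(c("A", "X"), prop)
  expect_equal(unname(rows[2, ]), rep(1 / 6, 6))
})

test_that("conservation scaling honours training bounds and guards", {
  expect_equal(conservation_track(c(0, 1, 2), c(0, 2)), c(0, 0.5, 1))
  # test-time values beyond the training range are clipped
  expect_equal(conservation_track(c(-1, 3), c(0, 2)), c(0, 1))
  # degenerate training range maps to the neutral 0.5
  expect_equal(conservation_track(c(5, 5, 5), c(5, 5)), rep(0.5, 3))
})

test_that("missing tracks are reported by name", {
  rec <- protein_record(id = "N", sequence = c("A", "C"),
                        pssm = matrix(0, 2, 20))
  expect_error(encode_protein(rec, 1, families = c("PSSM", "SS")), "SS")
  expect_error(encode_protein(rec, 1, families = "DISO"), "disorder")
  expect_error(encode_protein(rec, 1, families = "SCE"), "propensity")
})
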