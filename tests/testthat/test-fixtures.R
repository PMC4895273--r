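test_that("generation is byte-identical under a fixed seed", {
  spec <- fixture_spec(n_proteins = 2, length_range = c(30, 35), seed = 23)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixtures(spec, d1)
  generate_fixtures(spec, d2)
  files <- list.files(d1)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed changes the data
  generate_fixtures(fixture_spec(n_proteins = 2, length_range = c(30, 35),
                                 seed = 24), d2)
  expect_false(identical(readLines(file.path(d1, "SYN001.fasta")),
                         readLines(file.path(d2, "SYN001.fasta"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(simulate_records(fixture_spec(n_proteins = 2,
                                          length_range = c(30, 32))))
  expect_identical(runif(3), a)
})

test_that("all tracks of a loaded fixture protein agree in length", {
  for (rec in SMALL_RECORDS[1:3]) {
    n <- length(rec$sequence)
    expect_equal(nrow(rec$pssm), n)
    expect_equal(length(rec$info), n)
    expect_equal(nrow(rec$ss), n)
    expect_equal(nrow(rec$diso), n)
    expect_equal(length(rec$rsa), n)
    expect_equal(length(rec$polar), n)
  }
})

test_that("planted RSA survives the DSSP round trip within quantisation", {
  spec <- fixture_spec(n_proteins = 3, length_range = c(40, 50), seed = 31)
  dir <- tempfile()
  manifest <- generate_fixtures(spec, dir)
  planted <- simulate_records(spec)
  loaded <- load_manifest_records(manifest)
  tbl <- max_asa_table()
  for (i in seq_along(planted)) {
    # ACC was rounded to whole Angstroms: error bounded by 0.5 / maxASA
    bound <- 0.5 / unname(tbl[planted[[i]]$sequence]) + 1e-12
    expect_true(all(abs(loaded[[i]]$rsa - planted[[i]]$rsa) <= bound))
  }
})

test_that("null-signal fixtures carry no learnable relationship", {
  spec <- fixture_spec(n_proteins = 10, length_range = c(40, 60), seed = 47,
                       signal = "none")
  recs <- simulate_records(spec)
  # the planted RSA is independent of the latent code driving the features
  rsa <- unlist(lapply(recs, `[[`, "rsa"))
  diso <- unlist(lapply(recs, function(r) r$diso[, 1]))
  expect_lt(abs(cor(rsa, diso)), 0.1)
})

test_that("prediction quality degrades monotonically with label noise", {
  mean_pcc <- vapply(c(0.02, 0.1, 0.3), function(noise) {
    pccs <- vapply(1:5, function(rep) {
      spec <- fixture_spec(n_proteins = 8, length_range = c(40, 60),
                           seed = 100 * rep + round(1000 * noise),
                           noise_sd = noise)
      recs <- simulate_records(spec)
      train <- recs[1:6]; test <- recs[7:8]
      b <- train_final(train, half_width = 3, n_stages = 40,
                       max_depth = 3)
      ds <- encode_dataset(test, 3, propensity = b$propensity,
                           cs_bounds = b$cs_bounds)
      rsa_pcc(predict(b$model, ds$X), ds$y)
    }, numeric(1))
    mean(pccs)
  }, numeric(1))
  expect_true(all(diff(mean_pcc) < 0))
})

test_that("the worked example is stable and internally consistent", {
  rec <- worked_example()
  expect_equal(length(rec$sequence), 12)
  expect_equal(rec$sequence[7], "X")
  expect_identical(worked_example(), rec) # fully deterministic
  # expected side-chain classes stored beside the fixture
  known <- as.character(side_chain_class(rec$rsa, rec$polar))
  expect_equal(known, attr(rec, "expected_sce"))
  # hand-checkable PSSM-only encoding at l = 1: 60 columns, interior row
  # equals the normalised scores of positions i-1, i, i+1
  X <- encode_protein(rec, half_width = 1, families = "PSSM")
  expect_equal(dim(X), c(12, 60))
  expect_equal(unname(X[5, ]),
               unname(logistic_normalize(c(rec$pssm[4, ], rec$pssm[5, ],
                                           rec$pssm[6, ]))))
})
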