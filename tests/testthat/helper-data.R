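# Shared small synthetic datasets, built once per test run.

SMALL_SPEC <- fixture_spec(n_proteins = 10, length_range = c(40, 60),
                           seed = 42)
SMALL_RECORDS <- simulate_records(SMALL_SPEC)

small_training_matrix <- function(n = 200, p = 4, seed = 7) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- pmin(pmax(X[, 1] + 0.3 * X[, 2] + rnorm(n, sd = 0.05), 0), 1)
  list(X = X, y = y)
}

# Writes the sequence-side files of a record to a directory, returning the
# paths; uses the same writers as the fixture generator.
write_record_files <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, paste0(rec$id, ".fasta")),
    pssm = file.path(dir, paste0(rec$id, ".pssm")),
    ss2 = file.path(dir, paste0(rec$id, ".ss2")),
    diso = file.path(dir, paste0(rec$id, ".diso")))
  seqinr::write.fasta(list(rec$sequence), rec$id, paths$fasta)
  rsaboost:::write_pssm_file(rec, paths$pssm)
  rsaboost:::write_ss2_file(rec, paths$ss2)
  rsaboost:::write_diso_file(rec, paths$diso)
  paths
}
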