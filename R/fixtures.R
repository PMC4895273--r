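# Kyte-Doolittle hydropathy, used only to draw polar fractions that are
# anti-correlated with hydrophobicity in the synthetic proteins.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Centered moving average with shrinking windows at the termini.
ma_partial <- function(u, span) {
  h <- span %/% 2L
  cs <- cumsum(c(0, u))
  i <- seq_along(u)
  lo <- pmax(1L, i - h); hi <- pmin(length(u), i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Synthetic-fixture specification
#'
#' Describes a batch of synthetic proteins with a planted, tunable
#' relationship between the sequence-side feature tracks and RSA. Every
#' residue carries a latent local code \eqn{u_i \sim U(0,1)}; the RSA is a
#' noisy neighbourhood average of the code
#' (`signal = "burial_code"`), so that recovering it rewards window lengths
#' covering the smoothing span, while each per-residue feature track (PSSM
#' signal columns, secondary structure, disorder, conservation) encodes the
#' *local* \eqn{u_i} only.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length.
#' @param seed Seed for the generator (single RNG stream; restored on
#'   exit).
#' @param noise_sd Gaussian noise added to the planted RSA.
#' @param signal `"burial_code"` (default), `"linear_mix"` (RSA mixes the
#'   neighbourhood average with the local code) or `"none"` (RSA independent
#'   of all features).
#' @param window_span Residues over which the planted RSA averages the
#'   local code (default 7, i.e. dependency spanning +/-3 neighbours).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 20L, length_range = c(80L, 120L),
                         seed = 1L, noise_sd = 0.05,
                         signal = c("burial_code", "linear_mix", "none"),
                         window_span = 7L) {
  signal <- match.arg(signal)
  stopifnot(n_proteins >= 1L, noise_sd >= 0, window_span >= 1L,
            length_range[1] >= window_span,
            length_range[2] >= length_range[1])
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 signal = signal, window_span = as.integer(window_span)),
            class = "fixture_spec")
}

simulate_protein <- function(id, len, spec, table) {
  u <- stats::runif(len)
  b <- clamp01(0.5 + 3 * (ma_partial(u, spec$window_span) - 0.5))
  rsa <- switch(spec$signal,
    burial_code = clamp01(b + stats::rnorm(len, sd = spec$noise_sd)),
    linear_mix = clamp01(0.5 + 2.4 * (0.7 * ma_partial(u, spec$window_span) +
                                        0.3 * u - 0.5) +
                           stats::rnorm(len, sd = spec$noise_sd)),
    none = stats::runif(len))
  sequence <- sample(AA20, len, replace = TRUE)

  pssm <- matrix(sample(-3:3, len * 20L, replace = TRUE), len, 20L)
  sig <- round(6 * (2 * u - 1)) + sample(-1:1, len, replace = TRUE)
  for (j in 1:5) pssm[, j] <- pmax(pmin(sig + sample(-1:1, len, TRUE), 9L), -9L)
  colnames(pssm) <- AA20

  pH <- clamp01(0.70 * (1 - u) + 0.10 + stats::rnorm(len, sd = 0.03))
  pE <- clamp01(0.20 * (1 - u) + 0.05 + stats::rnorm(len, sd = 0.03))
  pC <- clamp01(1 - pH - pE)
  pD <- clamp01(u + stats::rnorm(len, sd = 0.05))
  info <- round(2 * (1 - u) + stats::runif(len, 0, 0.3), 2)
  kd <- KD_HYDROPATHY[sequence] / 4.5
  polar <- clamp01(0.55 - 0.30 * kd + stats::rnorm(len, sd = 0.08))
  asa <- round(rsa * unname(table[sequence]))

  protein_record(id = id, sequence = sequence, pssm = pssm, info = info,
                 ss = cbind(C = round(pC, 3), H = round(pH, 3),
                            E = round(pE, 3)),
                 diso = cbind(diso = round(pD, 3), ord = round(1 - pD, 3)),
                 rsa = rsa, polar = round(polar, 3), asa = asa)
}

write_pssm_file <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ", paste(sprintf("%3s", c(AA20, AA20)),
                                           collapse = ""))), con)
  for (i in seq_along(rec$sequence)) {
    writeLines(paste0(sprintf("%5d %s ", i, rec$sequence[i]),
                      paste(sprintf("%3d", rec$pssm[i, ]), collapse = ""),
                      " ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = ""),
                      sprintf("  %4.2f %8.2f", rec$info[i], 0)), con)
  }
  writeLines("", con)
}

write_ss2_file <- function(rec, path) {
  states <- c("C", "H", "E")[max.col(rec$ss, ties.method = "first")]
  lines <- c("# PSIPRED VFORMAT (synthetic)", "",
             sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                     seq_along(rec$sequence), rec$sequence, states,
                     rec$ss[, 1], rec$ss[, 2], rec$ss[, 3]))
  writeLines(lines, path)
}

write_diso_file <- function(rec, path) {
  lines <- c("# synthetic per-residue disorder probabilities",
             sprintf("%5d %s %6.3f %6.3f", seq_along(rec$sequence),
                     rec$sequence, rec$diso[, 1], rec$diso[, 2]))
  writeLines(lines, path)
}

write_dssp_file <- function(rec, path) {
  # DSSP-minimal dialect: only the columns the parser reads are populated
  # (chain at column 12, residue code at 14, ACC at 35-38).
  lines <- c("==== Secondary Structure Definition (synthetic DSSP-minimal dialect) ====",
             sprintf("%5d %d %d %d %d  TOTAL NUMBER OF RESIDUES",
                     length(rec$sequence), 1L, 0L, 0L, 0L),
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA",
             sprintf("%5d%5d %1s %1s%20s%4d", seq_along(rec$sequence),
                     seq_along(rec$sequence), "A", rec$sequence, "",
                     rec$asa))
  writeLines(lines, path)
}

write_polar_file <- function(rec, path) {
  utils::write.table(data.frame(id = rec$id,
                                index = seq_along(rec$sequence),
                                F = rec$polar),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a synthetic fixture dataset on disk
#'
#' Writes, for every synthetic protein, a FASTA file, a PSI-BLAST-dialect
#' ASCII PSSM, a PSIPRED-style `.ss2`, a DISOPRED-style disorder file, a
#' DSSP-minimal-dialect file (ACC = planted RSA times the residue's maximum
#' accessibility) and a polar-fraction sidecar, all mutually consistent and
#' readable by the package's parsers, plus a `manifest.tsv`. Byte-identical
#' output for identical spec and seed.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @param table [max_asa_table()] used to quantise ACC values.
#' @return Path to the written manifest, invisibly.
#' @export
generate_fixtures <- function(spec = fixture_spec(), outdir,
                              table = max_asa_table()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  records <- simulate_records(spec, table)
  rows <- lapply(records, function(rec) {
    id <- rec$id
    seqinr::write.fasta(list(rec$sequence), id,
                        file.path(outdir, paste0(id, ".fasta")))
    write_pssm_file(rec, file.path(outdir, paste0(id, ".pssm")))
    write_ss2_file(rec, file.path(outdir, paste0(id, ".ss2")))
    write_diso_file(rec, file.path(outdir, paste0(id, ".diso")))
    write_dssp_file(rec, file.path(outdir, paste0(id, ".dssp")))
    write_polar_file(rec, file.path(outdir, paste0(id, ".polar.tsv")))
    data.frame(id = id, fasta = paste0(id, ".fasta"),
               pssm = paste0(id, ".pssm"), ss2 = paste0(id, ".ss2"),
               diso = paste0(id, ".diso"), dssp = paste0(id, ".dssp"),
               polar = paste0(id, ".polar.tsv"))
  })
  manifest <- file.path(outdir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Simulate fixture records in memory
#'
#' Same generator as [generate_fixtures()] without touching disk; the
#' planted RSA is carried on the records exactly (no ACC quantisation).
#'
#' @inheritParams generate_fixtures
#' @return List of `protein_record`s.
#' @export
simulate_records <- function(spec = fixture_spec(), table = max_asa_table()) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                 spec$n_proteins, replace = TRUE)
  lapply(seq_len(spec$n_proteins), function(i) {
    simulate_protein(sprintf("SYN%03d", i), lens[i], spec, table)
  })
}

#' Hand-specified 12-residue example protein
#'
#' A fixed in-memory record (including one nonstandard `X` residue) with
#' small deterministic tracks, used throughout the unit tests and
#' documentation. The expected six-class side-chain environments of its
#' residues are attached as attribute `expected_sce`.
#'
#' @return A `protein_record` of length 12.
#' @examples
#' rec <- worked_example()
#' side_chain_class(rec$rsa, rec$polar)
#' @export
worked_example <- function() {
  sequence <- c("M", "K", "V", "L", "A", "G", "X", "W", "S", "D", "T", "E")
  pssm <- outer(1:12, 1:20, function(i, j) ((i * 3 + j * 7) %% 13) - 6)
  colnames(pssm) <- AA20
  info <- round(seq(0.2, 2.4, length.out = 12), 2)
  ss <- cbind(C = round(seq(0.10, 0.90, length.out = 12), 2),
              H = round(seq(0.80, 0.05, length.out = 12), 2),
              E = round(seq(0.05, 0.30, length.out = 12), 2))
  diso <- cbind(diso = round(seq(0.05, 0.95, length.out = 12), 2),
                ord = round(1 - seq(0.05, 0.95, length.out = 12), 2))
  rsa <- c(0.02, 0.10, 0.05, 0.00, 0.36, 0.20, 0.12, 0.08, 0.50, 0.35,
           0.09, 1.00)
  polar <- c(0.30, 0.70, 0.50, 0.60, 0.99, 0.70, 0.40, 0.44, 0.10, 0.66,
             0.67, 0.00)
  mx <- max_asa_table()
  asa <- round(rsa * unname(mx[sequence]))
  rec <- protein_record(id = "WORKED1", sequence = sequence, pssm = pssm,
                        info = info, ss = ss, diso = diso, rsa = rsa,
                        polar = polar, asa = asa)
  attr(rec, "expected_sce") <- c("B1", "P2", "B2", "B3", "E", "P2", "P1",
                                 "B1", "E", "P1", "P2", "E")
  rec
}
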