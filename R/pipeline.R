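#' Read a dataset manifest
#'
#' A manifest is a tab-separated table with one protein per row and columns
#' `id`, `fasta`, `pssm`, `ss2`, `diso` plus optional `dssp` (labels) and
#' `polar` (polar-fraction sidecar). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return `data.frame` of file paths, one row per protein.
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "fasta", "pssm", "ss2", "diso")
  if (!all(need %in% names(d))) {
    stop("manifest ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(d) == 0L) stop("empty manifest: ", path)
  if (anyDuplicated(d$id)) {
    stop("duplicate protein id(s) in manifest: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (col in setdiff(names(d), "id")) {
    rel <- !is.na(d[[col]]) & nzchar(d[[col]]) &
      !grepl("^(/|[A-Za-z]:)", d[[col]])
    d[[col]][rel] <- file.path(base, d[[col]][rel])
  }
  d
}

#' Load one protein's files into a record
#'
#' Parses the FASTA, PSSM, `.ss2` and disorder files (cross-checking lengths
#' and residue letters), plus the DSSP file into RSA labels and the
#' polar-fraction sidecar when present.
#'
#' @param row One row of a [read_manifest()] table (list or 1-row
#'   data.frame).
#' @param table [max_asa_table()] used for RSA labelling.
#' @return A [protein_record()].
#' @export
load_protein <- function(row, table = max_asa_table()) {
  seq <- read_fasta_seq(row$fasta)
  pssm <- read_pssm(row$pssm, sequence = seq)
  ss <- read_ss2(row$ss2, sequence = seq)
  diso <- read_diso(row$diso, sequence = seq)
  rsa <- NULL; asa <- NULL
  if (!is.null(row$dssp) && !is.na(row$dssp) && nzchar(row$dssp)) {
    lab <- rsa_from_dssp(row$dssp, table = table)
    if (nrow(lab) != length(seq)) {
      stop("DSSP track of protein ", row$id, " has ", nrow(lab),
           " residues but the sequence has ", length(seq))
    }
    rsa <- lab$rsa; asa <- lab$asa
  }
  polar <- NULL
  if (!is.null(row$polar) && !is.na(row$polar) && nzchar(row$polar)) {
    polar <- read_polar(row$polar, sequence = seq)
  }
  protein_record(id = row$id, sequence = seq, pssm = pssm$scores,
                 info = pssm$info, ss = ss, diso = diso, rsa = rsa,
                 polar = polar, asa = asa)
}

#' Load every protein of a manifest
#'
#' @param manifest Manifest path or a [read_manifest()] table.
#' @param table [max_asa_table()] for RSA labels.
#' @param permissive Skip malformed proteins with a warning instead of
#'   failing.
#' @param quiet Suppress the per-protein residue-count log.
#' @return List of `protein_record`s.
#' @export
load_manifest_records <- function(manifest, table = max_asa_table(),
                                  permissive = FALSE, quiet = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- as.list(manifest[i, ])
    rec <- if (permissive) {
      tryCatch(load_protein(row, table),
               error = function(e) {
                 warning("skipping protein ", row$id, ": ",
                         conditionMessage(e))
                 NULL
               })
    } else load_protein(row, table)
    if (is.null(rec)) next
    if (!quiet) message(rec$id, ": ", length(rec$sequence), " residues")
    records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L) stop("no loadable proteins in manifest")
  records
}

#' Assemble the encoded design matrix of a manifest
#'
#' Loads every protein, estimates the side-chain-environment propensity
#' table and conservation bounds from the loaded (labelled) records unless
#' they are supplied, and encodes all residues into one flat dataset.
#'
#' @inheritParams load_manifest_records
#' @inheritParams encode_protein
#' @return An `encoded_dataset` (see [encode_dataset()]) with the
#'   `propensity` and `cs_bounds` used attached as attributes.
#' @export
build_dataset <- function(manifest, half_width = 3L,
                          families = FEATURE_FAMILIES, propensity = NULL,
                          cs_bounds = NULL, table = max_asa_table(),
                          permissive = FALSE, quiet = TRUE) {
  records <- load_manifest_records(manifest, table, permissive, quiet)
  if (is.null(propensity) && "SCE" %in% families) {
    propensity <- sce_propensity(records)
  }
  if (is.null(cs_bounds) && "CS" %in% families) {
    cs_bounds <- conservation_bounds(unlist(lapply(records, `[[`, "info")))
  }
  ds <- encode_dataset(records, half_width, families, propensity, cs_bounds)
  attr(ds, "propensity") <- propensity
  attr(ds, "cs_bounds") <- cs_bounds
  ds
}

assign_folds <- function(ids, folds, seed) {
  if (length(ids) < folds) {
    stop("fewer proteins (", length(ids), ") than folds (", folds, ")")
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- rep(seq_len(folds), length.out = length(ids))[sample(length(ids))]
  names(fold) <- ids
  fold
}

fit_fold <- function(train_records, half_width, families, n_stages,
                     shrinkage, loss, max_depth, min_samples_leaf) {
  propensity <- if ("SCE" %in% families) sce_propensity(train_records)
  cs_bounds <- if ("CS" %in% families) {
    conservation_bounds(unlist(lapply(train_records, `[[`, "info")))
  }
  tr <- encode_dataset(train_records, half_width, families, propensity,
                       cs_bounds)
  keep <- !is.na(tr$y)
  model <- gbrt_fit(tr$X[keep, , drop = FALSE], tr$y[keep],
                    n_stages = n_stages, shrinkage = shrinkage, loss = loss,
                    max_depth = max_depth,
                    min_samples_leaf = min_samples_leaf,
                    column_labels = tr$column_labels)
  list(model = model, propensity = propensity, cs_bounds = cs_bounds)
}

#' Protein-level k-fold cross-validation
#'
#' Splits proteins (never residues — residue-level splits would leak
#' overlapping windows between train and test) into `folds` folds with a
#' seeded shuffle. Within each fold the side-chain-environment propensity
#' table and the conservation bounds are re-estimated from the training
#' proteins only, a model is trained, and the held-out residues are
#' predicted; metrics are pooled over all held-out residues.
#'
#' @param records List of labelled `protein_record`s.
#' @param half_width Window half width `l`.
#' @param n_stages Number of boosting stages `M`.
#' @param stage_grid Optional vector of stage counts at which to evaluate
#'   (staged prediction; defaults to `n_stages` only).
#' @param shrinkage,loss,max_depth,min_samples_leaf Passed to [gbrt_fit()].
#' @param families Feature families.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @return A `cv_result`: list with `metrics` (`data.frame` of `M`, `mae`,
#'   `rmse`, `pcc` pooled over held-out residues), `fold` (per-protein fold
#'   id), and `predictions` (per-residue `data.frame`: `id`, `index`,
#'   `residue`, `truth` and one prediction column per entry of
#'   `stage_grid`).
#' @export
cross_validate <- function(records, half_width = 3L, n_stages = 300L,
                           stage_grid = NULL, shrinkage = 0.1,
                           loss = loss_function("huber"), max_depth = 4L,
                           min_samples_leaf = 5L,
                           families = FEATURE_FAMILIES, folds = 5L,
                           seed = 1L) {
  ids <- vapply(records, `[[`, "", "id")
  fold <- assign_folds(ids, folds, seed)
  if (is.null(stage_grid)) stage_grid <- n_stages
  stage_grid <- sort(unique(as.integer(stage_grid)))
  stopifnot(all(stage_grid <= n_stages))

  preds <- list()
  for (k in seq_len(folds)) {
    train <- records[fold[ids] != k]
    test <- records[fold[ids] == k]
    ft <- fit_fold(train, half_width, families, n_stages, shrinkage, loss,
                   max_depth, min_samples_leaf)
    te <- encode_dataset(test, half_width, families, ft$propensity,
                         ft$cs_bounds)
    sp <- staged_predict(ft$model, te$X, stages = stage_grid)
    colnames(sp) <- paste0("pred_M", stage_grid)
    idx <- unlist(lapply(test, function(r) seq_along(r$sequence)))
    preds[[k]] <- cbind(data.frame(id = te$groups, index = idx,
                                   residue = te$residues, truth = te$y),
                        as.data.frame(sp))
  }
  preds <- do.call(rbind, preds)
  labelled <- !is.na(preds$truth)
  metrics <- do.call(rbind, lapply(stage_grid, function(m) {
    p <- preds[[paste0("pred_M", m)]][labelled]
    t <- preds$truth[labelled]
    data.frame(M = m, mae = rsa_mae(p, t), rmse = rsa_rmse(p, t),
               pcc = rsa_pcc(p, t))
  }))
  structure(list(metrics = metrics, fold = fold, predictions = preds,
                 half_width = half_width, seed = seed),
            class = "cv_result")
}

#' Grid search over window length and stage count
#'
#' Runs [cross_validate()] for every window length `L` of the grid, training
#' once per (fold, L) at the largest `M` and evaluating all smaller stage
#' counts from the staged predictions. Returns the full performance surface
#' and the selected pair.
#'
#' @param records Labelled `protein_record`s.
#' @param window_lengths Odd window lengths `L` to scan (default
#'   `seq(3, 17, 2)`).
#' @param stage_grid Stage counts `M` to scan (default
#'   `seq(100, 1500, 50)`).
#' @param criterion Model selection criterion over pooled CV metrics:
#'   minimise `"mae"` (default) or maximise `"pcc"`. Ties are broken toward
#'   the smaller `M`, then the smaller `L` (the cheaper model).
#' @inheritParams cross_validate
#' @param ... Passed to [cross_validate()] (`shrinkage`, `loss`, etc.).
#' @return List with `surface` (`data.frame` of `L`, `M`, `mae`, `rmse`,
#'   `pcc`), `best` (list with `L`, `M`), and `criterion`.
#' @export
grid_search <- function(records, window_lengths = seq(3L, 17L, 2L),
                        stage_grid = seq(100L, 1500L, 50L),
                        criterion = c("mae", "pcc"), folds = 5L, seed = 1L,
                        ...) {
  criterion <- match.arg(criterion)
  if (any(window_lengths %% 2L != 1L)) {
    stop("window lengths must be odd (L = 2l + 1)")
  }
  surface <- do.call(rbind, lapply(window_lengths, function(L) {
    cv <- cross_validate(records, half_width = (L - 1L) %/% 2L,
                         n_stages = max(stage_grid),
                         stage_grid = stage_grid, folds = folds,
                         seed = seed, ...)
    cbind(data.frame(L = L), cv$metrics)
  }))
  score <- if (criterion == "mae") surface$mae else -surface$pcc
  best <- surface[order(score, surface$M, surface$L), ][1, ]
  list(surface = surface, best = list(L = best$L, M = best$M),
       criterion = criterion)
}

#' Train a final prediction bundle
#'
#' Estimates the side-chain-environment propensity table and conservation
#' bounds on the full training set, encodes, fits the boosted model and
#' packages everything needed for sequence-only prediction: model, window
#' configuration, propensity table, conservation bounds and the identity of
#' the max-ASA table used for the training labels.
#'
#' @param records Labelled `protein_record`s.
#' @inheritParams cross_validate
#' @param table [max_asa_table()] whose identity is recorded in the bundle.
#' @return An `rsa_bundle`.
#' @export
train_final <- function(records, half_width = 3L, n_stages = 800L,
                        shrinkage = 0.1, loss = loss_function("huber"),
                        max_depth = 4L, min_samples_leaf = 5L,
                        families = FEATURE_FAMILIES,
                        table = max_asa_table()) {
  ft <- fit_fold(records, half_width, families, n_stages, shrinkage, loss,
                 max_depth, min_samples_leaf)
  structure(list(model = ft$model, half_width = as.integer(half_width),
                 families = families, propensity = ft$propensity,
                 cs_bounds = ft$cs_bounds,
                 max_asa_name = attr(table, "table_name")),
            class = "rsa_bundle")
}

#' @export
print.rsa_bundle <- function(x, ...) {
  cat("RSA prediction bundle: L =", 2L * x$half_width + 1L, ", M =",
      x$model$n_stages, ", families:", paste(x$families, collapse = "+"),
      ", max-ASA table:", x$max_asa_name, "\n")
  invisible(x)
}

#' Predict RSA for one protein from sequence-side files
#'
#' Needs only the FASTA, PSSM, `.ss2` and disorder files (no structure): the
#' side-chain environment enters through the bundle's propensity lookup.
#'
#' @param bundle An `rsa_bundle` from [train_final()] or [load_bundle()].
#' @param fasta,pssm,ss2,diso Paths to the protein's input files.
#' @param thresholds Percent thresholds at which to add two-state calls.
#' @return `data.frame` with `index`, `residue`, `rsa_pred` and one
#'   `state_<t>` column per threshold.
#' @export
predict_protein <- function(bundle, fasta, pssm, ss2, diso,
                            thresholds = c(5, 10, 20, 25, 30, 40, 50)) {
  seq <- read_fasta_seq(fasta)
  prof <- read_pssm(pssm, seq)
  rec <- protein_record(id = attr(seq, "id"), sequence = seq,
                        pssm = prof$scores, info = prof$info,
                        ss = read_ss2(ss2, seq), diso = read_diso(diso, seq))
  X <- encode_protein(rec, bundle$half_width, bundle$families,
                      bundle$propensity, bundle$cs_bounds)
  rsa <- predict(bundle$model, X)
  out <- data.frame(index = seq_along(seq), residue = seq, rsa_pred = rsa)
  for (th in thresholds) {
    out[[paste0("state_", th)]] <- as.character(two_state(rsa, th))
  }
  out
}

#' Evaluate a bundle on labelled proteins
#'
#' Encodes the labelled records with the bundle's (training-time) propensity
#' table and conservation bounds, predicts, and reports real-value and
#' two-state performance over the pooled residues.
#'
#' @param bundle An `rsa_bundle`.
#' @param records Labelled `protein_record`s (or a manifest path with
#'   `dssp` columns).
#' @param thresholds Percent thresholds for the two-state table.
#' @return List with `real` (see [real_value_report()]), `two_state`
#'   (see [two_state_table()]) and `n`.
#' @export
evaluate_bundle <- function(bundle, records,
                            thresholds = c(5, 10, 20, 25, 30, 40, 50)) {
  if (is.character(records)) records <- load_manifest_records(records)
  ds <- encode_dataset(records, bundle$half_width, bundle$families,
                       bundle$propensity, bundle$cs_bounds)
  keep <- !is.na(ds$y)
  pred <- predict(bundle$model, ds$X[keep, , drop = FALSE])
  list(real = real_value_report(pred, ds$y[keep]),
       two_state = two_state_table(pred, ds$y[keep], thresholds),
       n = sum(keep))
}

#' Save / load a prediction bundle
#'
#' The bundle (model, window configuration, propensity table, conservation
#' bounds, max-ASA table identity) is written as one versioned JSON document
#' at full numeric precision; reloaded bundles predict bit-identically.
#'
#' @param bundle An `rsa_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  doc <- list(format = "rsaboost-bundle-1",
              model = gbrt_serialize_list(bundle$model),
              half_width = bundle$half_width, families = bundle$families,
              propensity = if (is.null(bundle$propensity)) NULL else
                list(rows = rownames(bundle$propensity),
                     cols = colnames(bundle$propensity),
                     values = as.vector(bundle$propensity)),
              cs_bounds = bundle$cs_bounds,
              max_asa_name = bundle$max_asa_name)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(doc$format, "rsaboost-bundle-1")) {
    stop("unrecognised bundle format: ", deparse(doc$format))
  }
  propensity <- NULL
  if (!is.null(doc$propensity)) {
    propensity <- matrix(as.double(doc$propensity$values),
                         nrow = length(doc$propensity$rows),
                         dimnames = list(doc$propensity$rows,
                                         doc$propensity$cols))
  }
  structure(list(model = gbrt_deserialize_list(doc$model),
                 half_width = as.integer(doc$half_width),
                 families = as.character(doc$families),
                 propensity = propensity,
                 cs_bounds = as.double(doc$cs_bounds),
                 max_asa_name = doc$max_asa_name),
            class = "rsa_bundle")
}
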