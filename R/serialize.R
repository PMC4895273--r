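SERIAL_VERSION <- "rsaboost-gbrt-1"

gbrt_serialize_list <- function(model) {
  list(
    format = SERIAL_VERSION,
    f0 = model$f0, nu = model$nu,
    loss = list(kind = model$loss$kind, alpha = model$loss$alpha),
    n_stages = model$n_stages, deltas = model$deltas, p = model$p,
    max_depth = model$max_depth, min_samples_leaf = model$min_samples_leaf,
    column_labels = model$column_labels,
    stages = lapply(model$stages, function(st) {
      list(nodes = as.list(st$tree$nodes),
           n_leaves = st$tree$n_leaves,
           leaf_ids = as.integer(names(st$updates)),
           updates = unname(st$updates))
    }))
}

gbrt_deserialize_list <- function(doc) {
  if (!identical(doc$format, SERIAL_VERSION)) {
    stop("unrecognised model format: ", deparse(doc$format))
  }
  stages <- lapply(doc$stages, function(st) {
    nodes <- data.frame(feature = as.integer(st$nodes$feature),
                        threshold = as.double(st$nodes$threshold),
                        left = as.integer(st$nodes$left),
                        right = as.integer(st$nodes$right),
                        value = as.double(st$nodes$value),
                        n = as.integer(st$nodes$n),
                        gain = as.double(st$nodes$gain))
    tree <- structure(list(nodes = nodes, n_leaves = as.integer(st$n_leaves),
                           p = as.integer(doc$p), train_leaf = NULL),
                      class = "regression_tree")
    upd <- as.double(st$updates)
    names(upd) <- as.integer(st$leaf_ids)
    list(tree = tree, updates = upd)
  })
  structure(list(f0 = doc$f0, nu = doc$nu,
                 loss = loss_function(doc$loss$kind, doc$loss$alpha),
                 n_stages = as.integer(doc$n_stages),
                 deltas = as.double(unlist(doc$deltas)), stages = stages,
                 p = as.integer(doc$p), max_depth = as.integer(doc$max_depth),
                 min_samples_leaf = as.integer(doc$min_samples_leaf),
                 column_labels = if (is.null(doc$column_labels)) NULL else
                   as.character(doc$column_labels),
                 train_loss = NULL),
            class = "gbrt")
}

#' Serialise a boosted model to JSON
#'
#' Writes a versioned JSON document holding the initial value, shrinkage,
#' loss specification, per-stage transition points and flattened tree arrays
#' (node feature/threshold/children/value/gain plus per-leaf updates).
#' Numbers are written at full precision so the round trip through
#' [gbrt_from_json()] is lossless: reloaded models produce bit-identical
#' predictions.
#'
#' @param model A `gbrt` model.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) when writing to file, else a JSON string.
#' @export
gbrt_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(gbrt_serialize_list(model), digits = I(17),
                         auto_unbox = TRUE, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Restore a boosted model from JSON
#'
#' @param input A file path or JSON string produced by [gbrt_to_json()].
#' @return A `gbrt` model.
#' @export
gbrt_from_json <- function(input) {
  doc <- jsonlite::fromJSON(input, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  gbrt_deserialize_list(doc)
}
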