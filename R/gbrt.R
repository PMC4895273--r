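#' Fit a gradient boosted regression trees model
#'
#' Stagewise additive modelling: starting from the constant
#' \eqn{F_0 = \arg\min_\beta \sum_i \Psi(y_i, \beta)}, each of `n_stages`
#' iterations (1) sets the Huber transition point \eqn{\delta_m} to the
#' `alpha`-quantile of the absolute current residuals, (2) computes
#' negative-gradient pseudo-residuals, (3) fits a least-squares regression
#' tree to them, (4) replaces each leaf value by the exact line-search
#' minimiser of the leaf loss on the true residuals, and (5) updates
#' \eqn{F_m = F_{m-1} + \nu \cdot u_{\mathrm{leaf}(x)}} with shrinkage
#' \eqn{\nu}. Fitting is deterministic given the data and configuration:
#' there is no subsampling and split ties are broken by a fixed rule.
#'
#' @param X Numeric feature matrix, one row per sample; all values finite.
#' @param y Numeric target vector (for RSA prediction, fractions in
#'   `[0, 1]`); all values finite.
#' @param n_stages Number of boosting iterations `M` (>= 0).
#' @param shrinkage Learning rate \eqn{\nu} in `(0, 1]`.
#' @param loss A [loss_function()] or its name (`"huber"` default).
#' @param max_depth Depth cap of each tree.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param column_labels Optional character vector of feature names (used by
#'   [feature_importance()] family aggregation and serialisation).
#' @return A `gbrt` model: list with `f0`, `nu`, `loss`, `n_stages`,
#'   `deltas`, `stages` (trees and per-leaf updates), `p`, `column_labels`
#'   and a `train_loss` trace (per-stage loss before/after, at that stage's
#'   transition point).
#' @seealso [predict.gbrt()], [staged_predict()], [feature_importance()],
#'   [gbrt_to_json()]
#' @examples
#' set.seed(1)
#' X <- matrix(runif(60), ncol = 2)
#' y <- pmin(pmax(X[, 1] + rnorm(30, sd = 0.05), 0), 1)
#' fit <- gbrt_fit(X, y, n_stages = 20, shrinkage = 0.3, max_depth = 2)
#' cor(predict(fit, X), y)
#' @export
gbrt_fit <- function(X, y, n_stages = 800L, shrinkage = 0.1,
                     loss = loss_function("huber"), max_depth = 4L,
                     min_samples_leaf = 5L, column_labels = NULL) {
  X <- as.matrix(X)
  loss <- as_loss(loss)
  if (nrow(X) != length(y)) {
    stop("nrow(X) (", nrow(X), ") != length(y) (", length(y), ")")
  }
  if (length(y) == 0L) stop("empty training set")
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  if (!all(is.finite(y))) stop("non-finite values in target vector")
  if (shrinkage <= 0 || shrinkage > 1) stop("'shrinkage' must be in (0, 1]")
  if (n_stages < 0L) stop("'n_stages' must be >= 0")
  storage.mode(X) <- "double"
  y <- as.double(y)
  n <- length(y)

  f0 <- initial_value(y, loss)
  f <- rep(f0, n)
  stages <- vector("list", n_stages)
  deltas <- rep(NA_real_, n_stages)
  loss_before <- loss_after <- rep(NA_real_, n_stages)

  for (m in seq_len(n_stages)) {
    delta_m <- if (loss$kind == "huber") huber_delta(y - f, loss$alpha) else NA_real_
    pr <- pseudo_residuals(y, f, loss, delta_m)
    tree <- fit_regression_tree(X, pr, max_depth = max_depth,
                                min_samples_leaf = min_samples_leaf)
    upd <- leaf_updates(tree, y, f, loss, delta_m)
    loss_before[m] <- total_loss(y, f, loss, delta_m)
    f <- f + shrinkage * unname(upd[match(tree$train_leaf,
                                          as.integer(names(upd)))])
    loss_after[m] <- total_loss(y, f, loss, delta_m)
    deltas[m] <- delta_m
    tree$train_leaf <- NULL
    stages[[m]] <- list(tree = tree, updates = upd)
  }

  structure(list(f0 = f0, nu = shrinkage, loss = loss,
                 n_stages = as.integer(n_stages), deltas = deltas,
                 stages = stages, p = ncol(X),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 column_labels = column_labels,
                 train_loss = data.frame(stage = seq_len(n_stages),
                                         delta = deltas,
                                         loss_before = loss_before,
                                         loss_after = loss_after)),
            class = "gbrt")
}

#' @export
print.gbrt <- function(x, ...) {
  cat("Gradient boosted regression trees model\n")
  cat("  stages:", x$n_stages, " shrinkage:", x$nu,
      " loss:", x$loss$kind, "\n")
  cat("  features:", x$p, " tree depth cap:", x$max_depth, "\n")
  invisible(x)
}

check_model_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop("feature count mismatch: model expects ", model$p,
         " columns, got ", ncol(X))
  }
  storage.mode(X) <- "double"
  X
}

#' Predict RSA values with a boosted model
#'
#' Evaluates \eqn{F_M(x) = F_0 + \nu \sum_m u_{m,\mathrm{leaf}_m(x)}}. By
#' default predictions are clipped to `[0, 1]`, the range of relative
#' solvent accessibility; set `clip = FALSE` for the raw additive output.
#'
#' @param object A `gbrt` model.
#' @param newdata Feature matrix with the training number of columns.
#' @param n_stages Evaluate the model truncated to its first `n_stages`
#'   trees (default: all).
#' @param clip Clip predictions to `[0, 1]` (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gbrt <- function(object, newdata, n_stages = NULL, clip = TRUE, ...) {
  m <- if (is.null(n_stages)) object$n_stages else as.integer(n_stages)
  if (m < 0L || m > object$n_stages) {
    stop("'n_stages' must be in [0, ", object$n_stages, "]")
  }
  out <- staged_predict(object, newdata, stages = m, clip = clip)
  out[, 1L]
}

#' Predictions at several stage counts in one pass
#'
#' @param model A `gbrt` model.
#' @param X Feature matrix.
#' @param stages Integer vector of stage counts (each in `[0, n_stages]`).
#' @param clip Clip predictions to `[0, 1]`.
#' @return Numeric matrix, `nrow(X)` rows, one column per entry of `stages`
#'   (column names = stage counts).
#' @export
staged_predict <- function(model, X, stages = seq_len(model$n_stages),
                           clip = TRUE) {
  X <- check_model_matrix(model, X)
  stages <- as.integer(stages)
  if (any(stages < 0L | stages > model$n_stages)) {
    stop("'stages' must all be in [0, ", model$n_stages, "]")
  }
  f <- rep(model$f0, nrow(X))
  out <- matrix(NA_real_, nrow(X), length(stages),
                dimnames = list(NULL, stages))
  hit <- function(m) {
    for (k in which(stages == m)) {
      out[, k] <<- if (clip) pmin(pmax(f, 0), 1) else f
    }
  }
  hit(0L)
  for (m in seq_len(max(stages, 0L))) {
    st <- model$stages[[m]]
    ids <- tree_leaf_ids(st$tree, X)
    f <- f + model$nu * unname(st$updates[match(ids,
                                                as.integer(names(st$updates)))])
    hit(m)
  }
  out
}

#' Split-gain feature importance
#'
#' Sums the squared-error reduction of every split over all trees, grouped
#' by feature column, and normalises the result to sum to 1. A model with no
#' splits at all returns uniform zeros.
#'
#' @param model A `gbrt` model.
#' @param by_family Aggregate columns into feature families using the prefix
#'   of `column_labels` before the first `.` (e.g. `PSSM`, `SS`, `DISO`,
#'   `SCE`, `CS`). Requires labels.
#' @return Named numeric vector of non-negative weights summing to 1 (or all
#'   zero when the model has no splits).
#' @export
feature_importance <- function(model, by_family = FALSE) {
  imp <- numeric(model$p)
  for (st in model$stages) {
    nd <- st$tree$nodes
    internal <- !is.na(nd$feature)
    if (any(internal)) {
      g <- tapply(nd$gain[internal], nd$feature[internal], sum)
      imp[as.integer(names(g))] <- imp[as.integer(names(g))] + g
    }
  }
  if (!is.null(model$column_labels)) names(imp) <- model$column_labels
  if (sum(imp) > 0) imp <- imp / sum(imp)
  if (by_family) {
    if (is.null(model$column_labels)) {
      stop("family aggregation needs a model fitted with 'column_labels'")
    }
    fam <- sub("\\..*$", "", model$column_labels)
    imp <- vapply(split(imp, fam), sum, numeric(1))
  }
  imp
}
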