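#' Fit a CART regression tree
#'
#' Greedy top-down least-squares regression tree: at every node the best
#' axis-aligned split is found by an exhaustive scan over all features and
#' all midpoints between consecutive distinct sorted values, maximising the
#' squared-error reduction. Leaf values are the mean of the targets reaching
#' the leaf. Ties between equally good splits are broken toward the lowest
#' feature index, then the lowest threshold, so fitting is deterministic.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param targets Numeric target vector, `length(targets) == nrow(X)`.
#' @param max_depth Maximum tree depth (0 = a single leaf).
#' @param min_samples_leaf Minimum number of samples in each leaf.
#' @return A `regression_tree`: list with a flat node table `nodes`
#'   (columns `feature`, `threshold`, `left`, `right`, `value`, `n`, `gain`;
#'   `feature` is `NA` for leaves), `n_leaves`, and `train_leaf`, the leaf
#'   node id of each training row.
#' @examples
#' tr <- fit_regression_tree(matrix(c(0, 1)), c(0, 1), max_depth = 1)
#' predict_tree(tr, matrix(c(0.2, 0.9)))
#' @export
fit_regression_tree <- function(X, targets, max_depth = 4L,
                                min_samples_leaf = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training set")
  if (nrow(X) != length(targets)) {
    stop("nrow(X) (", nrow(X), ") != length(targets) (", length(targets), ")")
  }
  if (min_samples_leaf < 1L) stop("'min_samples_leaf' must be >= 1")
  storage.mode(X) <- "double"
  targets <- as.double(targets)

  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$threshold <- double(0)
  env$left <- integer(0); env$right <- integer(0)
  env$value <- double(0); env$n <- integer(0); env$gain <- double(0)
  env$train_leaf <- integer(nrow(X))

  new_node <- function() {
    id <- length(env$n) + 1L
    env$feature[id] <- NA_integer_; env$threshold[id] <- NA_real_
    env$left[id] <- NA_integer_; env$right[id] <- NA_integer_
    env$value[id] <- NA_real_; env$n[id] <- 0L; env$gain[id] <- 0
    id
  }

  build <- function(idx, depth) {
    id <- new_node()
    env$n[id] <- length(idx)
    t_idx <- targets[idx]
    make_leaf <- depth >= max_depth ||
      length(idx) < 2L * min_samples_leaf ||
      all(t_idx == t_idx[1])
    if (!make_leaf) {
      sp <- best_split_cpp(X, targets, idx, as.integer(min_samples_leaf))
      make_leaf <- !sp$found
    }
    if (make_leaf) {
      env$value[id] <- mean(t_idx)
      env$train_leaf[idx] <- id
      return(id)
    }
    env$feature[id] <- sp$feature
    env$threshold[id] <- sp$threshold
    env$gain[id] <- sp$gain
    go_left <- X[idx, sp$feature] <= sp$threshold
    env$left[id] <- build(idx[go_left], depth + 1L)
    env$right[id] <- build(idx[!go_left], depth + 1L)
    id
  }
  build(seq_len(nrow(X)), 0L)

  nodes <- data.frame(feature = env$feature, threshold = env$threshold,
                      left = env$left, right = env$right, value = env$value,
                      n = env$n, gain = env$gain)
  structure(list(nodes = nodes, n_leaves = sum(is.na(nodes$feature)),
                 p = ncol(X), train_leaf = env$train_leaf),
            class = "regression_tree")
}

#' Leaf membership of new samples
#'
#' Routes every row of `X` down the tree (left when
#' `x[feature] <= threshold`) and returns the id of the single leaf it
#' reaches. Leaf regions partition the feature space, so exactly one leaf is
#' reached per row.
#'
#' @param tree A `regression_tree`.
#' @param X Numeric matrix with the training number of columns.
#' @return Integer vector of leaf node ids, one per row of `X`.
#' @export
tree_leaf_ids <- function(tree, X) {
  X <- as.matrix(X)
  if (ncol(X) != tree$p) {
    stop("feature count mismatch: tree expects ", tree$p, " columns, got ",
         ncol(X))
  }
  nd <- tree$nodes
  out <- integer(nrow(X))
  stack <- list(list(id = 1L, idx = seq_len(nrow(X))))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    id <- top$id; idx <- top$idx
    if (length(idx) == 0L) next
    if (is.na(nd$feature[id])) { out[idx] <- id; next }
    go_left <- X[idx, nd$feature[id]] <= nd$threshold[id]
    stack[[length(stack) + 1L]] <- list(id = nd$left[id], idx = idx[go_left])
    stack[[length(stack) + 1L]] <- list(id = nd$right[id], idx = idx[!go_left])
  }
  out
}

#' Predict with a single regression tree
#'
#' @inheritParams tree_leaf_ids
#' @return Numeric vector of leaf values, one per row of `X`.
#' @export
predict_tree <- function(tree, X) {
  tree$nodes$value[tree_leaf_ids(tree, X)]
}

#' Per-leaf line-search updates for a boosting stage
#'
#' Given the tree of a boosting stage and the current residuals
#' `r = y - f`, computes the constant added in each leaf region. For squared
#' error the optimal constant is the mean residual of the leaf. For Huber
#' loss it is the exact minimiser of the leaf Huber loss
#' \eqn{\sum_i \Psi_\delta(r_i - u)}, obtained by solving the monotone
#' piecewise-linear equation \eqn{\sum_i \mathrm{clip}(r_i - u, \pm\delta)=0}.
#' These per-leaf constants subsume the global stage weight of the generic
#' gradient-boosting formulation: a separate scalar line search cannot beat
#' per-region optima.
#'
#' @param tree A `regression_tree` from [fit_regression_tree()].
#' @param y,f Observed targets and current model fit on the training rows.
#' @param loss A [loss_function()] or its name.
#' @param delta Huber transition point of this stage.
#' @param leaf_ids Leaf membership of the training rows; defaults to the
#'   membership recorded during fitting.
#' @return Named numeric vector of updates, names = leaf node ids.
#' @export
leaf_updates <- function(tree, y, f, loss = loss_function("huber"),
                         delta = NULL, leaf_ids = tree$train_leaf) {
  loss <- as_loss(loss)
  stopifnot(length(y) == length(f), length(leaf_ids) == length(y))
  r <- y - f
  leaves <- sort(unique(leaf_ids))
  upd <- vapply(leaves, function(id) {
    rl <- r[leaf_ids == id]
    if (loss$kind == "squared") mean(rl) else huber_leaf_optimum(rl, delta)
  }, numeric(1))
  names(upd) <- leaves
  upd
}
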