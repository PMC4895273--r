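test_that("degenerate inputs give single-leaf trees or errors", {
  tr <- fit_regression_tree(matrix(0.5), 0.7)
  expect_equal(tr$n_leaves, 1L)
  expect_equal(predict_tree(tr, matrix(c(-10, 10))), c(0.7, 0.7))
  # identical targets: no split regardless of depth budget
  tr2 <- fit_regression_tree(matrix(runif(20), ncol = 2), rep(0.4, 10),
                             max_depth = 5)
  expect_equal(tr2$n_leaves, 1L)
  expect_error(fit_regression_tree(matrix(numeric(0), 0, 1), numeric(0)),
               "empty")
})

test_that("a separable pair is split at the midpoint with zero error", {
  tr <- fit_regression_tree(matrix(c(0, 1)), c(0, 1), max_depth = 1)
  nd <- tr$nodes
  expect_equal(nd$threshold[1], 0.5)
  expect_equal(sort(nd$value[is.na(nd$feature)]), c(0, 1))
  expect_equal(predict_tree(tr, matrix(c(0.4, 0.6))), c(0, 1))
})

test_that("depth-2 fit equals exhaustive enumeration over all split pairs", {
  # four plateaus: the optimal depth-2 tree is unique
  x <- matrix(1:8, ncol = 1)
  y <- c(0, 0, 1, 1, 4, 4, 5, 5)
  tr <- fit_regression_tree(x, y, max_depth = 2)

  # oracle: enumerate every (root, left, right) split-point combination
  mids <- (1:7) + 0.5
  best <- list(sse = Inf)
  part_sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  for (s0 in mids) {
    li <- x[, 1] <= s0
    for (s1 in c(NA, mids[mids < s0])) {
      for (s2 in c(NA, mids[mids > s0])) {
        yl <- y[li]; yr <- y[!li]
        sse <- 0
        sse <- sse + if (is.na(s1)) part_sse(yl) else
          part_sse(yl[x[li, 1] <= s1]) + part_sse(yl[x[li, 1] > s1])
        sse <- sse + if (is.na(s2)) part_sse(yr) else
          part_sse(yr[x[!li, 1] <= s2]) + part_sse(yr[x[!li, 1] > s2])
        if (sse < best$sse) best <- list(sse = sse, s = c(s0, s1, s2))
      }
    }
  }
  fitted_sse <- sum((predict_tree(tr, x) - y)^2)
  expect_equal(fitted_sse, best$sse)
  expect_setequal(tr$nodes$threshold[!is.na(tr$nodes$feature)], best$s)
})

test_that("tree tie-breaking prefers the lowest feature index", {
  # two identical columns: both give the same gain; column 1 must win
  X <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1))
  tr <- fit_regression_tree(X, c(0, 0, 1, 1), max_depth = 1)
  expect_equal(tr$nodes$feature[1], 1L)
})

test_that("leaf regions partition the input space", {
  set.seed(3)
  X <- matrix(runif(400), ncol = 4)
  tr <- fit_regression_tree(X, rowSums(X) + rnorm(100, sd = 0.1),
                            max_depth = 4, min_samples_leaf = 3)
  nd <- tr$nodes
  leaves <- which(is.na(nd$feature))

  # independent region check: collect each leaf's box constraints by
  # walking every root-to-leaf path, then count containing boxes per point
  paths <- list()
  walk <- function(id, lo, hi) {
    if (is.na(nd$feature[id])) {
      paths[[as.character(id)]] <<- list(lo = lo, hi = hi)
      return(invisible())
    }
    j <- nd$feature[id]; t <- nd$threshold[id]
    hi2 <- hi; hi2[j] <- min(hi[j], t)
    lo2 <- lo; lo2[j] <- max(lo[j], t)
    walk(nd$left[id], lo, hi2)
    walk(nd$right[id], lo2, hi)
  }
  walk(1L, rep(-Inf, 4), rep(Inf, 4))

  P <- matrix(runif(4e4, -0.5, 1.5), ncol = 4)
  hits <- rowSums(vapply(paths, function(b) {
    apply(P, 1, function(x) all(x <= b$hi) && all(x > b$lo))
  }, logical(nrow(P))))
  expect_true(all(hits == 1))
  expect_true(all(tree_leaf_ids(tr, P) %in% leaves))
})

test_that("leaf updates solve the per-leaf line search", {
  X <- matrix(c(0, 0, 1), ncol = 1)
  tr <- fit_regression_tree(X, c(0.2, 0.2, 0.9), max_depth = 1)
  # squared loss: mean residual per leaf
  upd <- leaf_updates(tr, y = c(0.2, 0.2, 0.9), f = rep(0, 3), "squared")
  expect_equal(sort(unname(upd)), c(0.2, 0.9))
  # huber: grid oracle per leaf
  y <- c(0, 0.1, 0.9); f <- rep(0, 3)
  tr1 <- fit_regression_tree(matrix(rep(1, 3)), y, max_depth = 2)
  expect_equal(tr1$n_leaves, 1L) # constant feature, no split
  upd_h <- leaf_updates(tr1, y, f, "huber", delta = 0.2)
  opt <- grid_argmin(function(u) sum(huber_psi(y - u, 0.2)), -1, 1)
  expect_equal(unname(upd_h), opt, tolerance = 1e-3)
})
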