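# Independent oracles used across the suite. These reimplement quantities
# from first principles (brute force, direct substitution, enumeration) and
# deliberately share no code with the package internals they check.

# 1-D grid minimiser of an arbitrary scalar function.
grid_argmin <- function(fn, lo, hi, step = 1e-4) {
  g <- seq(lo, hi, by = step)
  g[which.min(vapply(g, fn, numeric(1)))]
}

# Huber loss evaluated directly from its two-branch definition.
huber_psi <- function(e, delta) {
  ifelse(abs(e) <= delta, 0.5 * e^2, delta * (abs(e) - delta / 2))
}

# Type-7 quantile written out long-hand: linear interpolation between
# order statistics at index h = (n - 1) * p.
quantile_type7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Naive stagewise boosting with depth-1 trees, squared loss, nu = 1 and
# exhaustive stump search; returns the staged prediction matrix
# (columns = 0..M stages). Splits need strictly positive error reduction,
# scanning features then thresholds in ascending order.
naive_stump_boost <- function(X, y, M) {
  n <- nrow(X)
  f <- rep(mean(y), n)
  preds <- matrix(NA_real_, n, M + 1)
  preds[, 1] <- f
  for (m in seq_len(M)) {
    r <- y - f
    sse_parent <- sum((r - mean(r))^2)
    best_sse <- sse_parent
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2) next
      for (k in seq_len(length(xs) - 1)) {
        thr <- (xs[k] + xs[k + 1]) / 2
        left <- X[, j] <= thr
        sse <- sum((r[left] - mean(r[left]))^2) +
          sum((r[!left] - mean(r[!left]))^2)
        if (sse < best_sse) {
          best_sse <- sse
          best <- list(left = left)
        }
      }
    }
    f <- f + if (is.null(best)) mean(r) else
      ifelse(best$left, mean(r[best$left]), mean(r[!best$left]))
    preds[, m + 1] <- f
  }
  preds
}

# Two-pass Pearson correlation by direct substitution into the
# covariance / (sd * sd) definition.
pcc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Phi coefficient as the plain correlation of the expanded binary vectors.
phi_oracle <- function(tp, tn, fp, fn) {
  x <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  y <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  suppressWarnings(stats::cor(x, y))
}

# Independent side-chain environment classifier, written as literal nested
# branches of the class definition.
sce_oracle <- function(rsa, f) {
  if (rsa >= 0.36) return("E")
  if (rsa >= 0.09) {
    if (f < 0.67) return("P1") else return("P2")
  }
  if (f < 0.45) return("B1")
  if (f < 0.58) return("B2")
  "B3"
}
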