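#' Construct a boosting loss specification
#'
#' The boosting learner supports a robust Huber loss (the default used for
#' RSA prediction) and plain squared error (mainly useful for oracle testing,
#' where every stage of the algorithm has a closed form).
#'
#' The Huber loss is quadratic for residuals within a transition point
#' \eqn{\delta} and linear beyond it:
#' \deqn{\Psi(y, F) = \frac{1}{2}(y-F)^2 \quad \mathrm{if}\ |y-F| \le \delta,
#'       \qquad \delta(|y-F| - \delta/2) \quad \mathrm{otherwise.}}
#' \eqn{\delta} is not fixed: it is recomputed at every boosting iteration as
#' the `alpha`-quantile of the absolute residuals (see [huber_delta()]).
#'
#' @param kind `"huber"` or `"squared"`.
#' @param alpha Quantile of the absolute residuals used to set the Huber
#'   transition point each iteration; in `(0, 1]`. Ignored for squared loss.
#' @return A `loss_function` object (list with `kind` and `alpha`).
#' @examples
#' loss_function("huber", alpha = 0.9)
#' loss_function("squared")
#' @export
loss_function <- function(kind = c("huber", "squared"), alpha = 0.9) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("'alpha' must be a single value in (0, 1]")
  }
  structure(list(kind = kind, alpha = alpha), class = "loss_function")
}

as_loss <- function(loss) {
  if (inherits(loss, "loss_function")) return(loss)
  if (is.character(loss) && length(loss) == 1L) return(loss_function(loss))
  stop("'loss' must be a loss_function or one of \"huber\", \"squared\"")
}

#' Total loss of a fit
#'
#' @param y,f Observed and fitted values (equal length).
#' @param loss A [loss_function()] or its name.
#' @param delta Huber transition point (required for Huber loss).
#' @return Scalar total loss \eqn{\sum_i \Psi(y_i, f_i)}.
#' @export
total_loss <- function(y, f, loss, delta = NULL) {
  loss <- as_loss(loss)
  stopifnot(length(y) == length(f))
  r <- y - f
  if (loss$kind == "squared") return(sum(0.5 * r^2))
  if (is.null(delta)) stop("'delta' is required for Huber loss")
  a <- abs(r)
  sum(ifelse(a <= delta, 0.5 * r^2, delta * (a - delta / 2)))
}

#' Initial constant of the boosted model
#'
#' The additive model starts from the constant minimising the total loss:
#' the mean for squared error, the median for Huber loss (the standard robust
#' initialiser; the exact Huber minimiser depends on a transition point that
#' is undefined before any residuals exist).
#'
#' @param y Numeric target vector (non-empty).
#' @inheritParams total_loss
#' @return A scalar starting value.
#' @export
initial_value <- function(y, loss = loss_function("huber")) {
  loss <- as_loss(loss)
  if (length(y) == 0L) stop("empty training set")
  if (loss$kind == "squared") mean(y) else stats::median(y)
}

#' Negative-gradient pseudo-residuals
#'
#' For squared error the pseudo-residual is the plain residual `y - f`.
#' For Huber loss the residual is clipped at the transition point:
#' `y - f` where `|y - f| <= delta`, and `delta * sign(y - f)` beyond it.
#'
#' @param y,f Observed and current fitted values (equal length).
#' @inheritParams total_loss
#' @return Numeric vector of pseudo-residuals, same length as `y`.
#' @export
pseudo_residuals <- function(y, f, loss = loss_function("huber"),
                             delta = NULL) {
  loss <- as_loss(loss)
  if (length(y) != length(f)) {
    stop("'y' and 'f' must have the same length (", length(y), " vs ",
         length(f), ")")
  }
  r <- y - f
  if (loss$kind == "squared") return(r)
  if (is.null(delta) || !is.finite(delta) || delta <= 0) {
    stop("'delta' must be a positive number for Huber loss")
  }
  pmax(pmin(r, delta), -delta)
}

#' Per-iteration Huber transition point
#'
#' The transition point changes with the boosting iteration: it is the
#' `alpha`-quantile of the absolute current residuals, floored at a small
#' positive epsilon so that a perfect interim fit does not collapse the loss.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention used throughout the package.
#'
#' @param residuals Numeric vector of current residuals (non-empty).
#' @param alpha Quantile level in `(0, 1]`.
#' @param eps Positive floor; default `1e-12`.
#' @return Scalar transition point.
#' @export
huber_delta <- function(residuals, alpha = 0.9, eps = 1e-12) {
  if (length(residuals) == 0L) stop("empty residual vector")
  d <- unname(stats::quantile(abs(residuals), probs = alpha, type = 7))
  max(d, eps)
}

# Exact per-leaf line search for Huber loss: the update u minimising
# sum_i Psi_delta(r_i - u) solves the monotone piecewise-linear estimating
# equation g(u) = sum_i clip(r_i - u, -delta, delta) = 0. g is continuous,
# non-increasing and linear between the knots r_i +/- delta; the leftmost
# root is found by linear interpolation between the bracketing knots.
huber_leaf_optimum <- function(r, delta) {
  n <- length(r)
  if (n == 1L) return(r)
  knots <- sort(c(r - delta, r + delta))
  g <- vapply(knots, function(u) sum(pmax(pmin(r - u, delta), -delta)),
              numeric(1))
  if (g[1] <= 0) return(knots[1])
  i <- max(which(g > 0))
  if (i == length(knots)) return(knots[i]) # cannot happen: g(max knot) <= 0
  # g is linear on [knots[i], knots[i+1]] with g[i] > 0 >= g[i+1]
  knots[i] + g[i] * (knots[i + 1] - knots[i]) / (g[i] - g[i + 1])
}
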