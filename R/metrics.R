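check_pair <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' must have the same length (", length(pred),
         " vs ", length(truth), ")")
  }
  if (length(pred) == 0L) stop("empty input")
}

#' Mean absolute error of RSA predictions (percent)
#'
#' Mean of `|pred - truth|` over all residues, reported in percent (inputs
#' are RSA fractions in `[0, 1]`).
#'
#' @param pred,truth Numeric vectors of equal nonzero length.
#' @return MAE in percent.
#' @examples
#' rsa_mae(c(0.2, 0.4), c(0.1, 0.5))
#' @export
rsa_mae <- function(pred, truth) {
  check_pair(pred, truth)
  100 * mean(abs(pred - truth))
}

#' Root mean square error of RSA predictions (percent)
#'
#' @inheritParams rsa_mae
#' @return RMSE in percent.
#' @export
rsa_rmse <- function(pred, truth) {
  check_pair(pred, truth)
  100 * sqrt(mean((pred - truth)^2))
}

#' Pearson correlation between predicted and experimental RSA
#'
#' Covariance of the two tracks divided by the product of their standard
#' deviations; 1 means fully correlated, 0 uncorrelated. A zero-variance
#' input is a defined error rather than a silent `NaN`.
#'
#' @inheritParams rsa_mae
#' @return Correlation in `[-1, 1]`.
#' @export
rsa_pcc <- function(pred, truth) {
  check_pair(pred, truth)
  if (length(pred) < 2L) stop("PCC needs at least two residues")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop("zero variance input: PCC is undefined")
  }
  stats::cor(pred, truth)
}

#' Matthews correlation coefficient from confusion counts
#'
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' with 0 returned when any factor of the denominator is zero (the standard
#' degenerate-table convention).
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_from_counts <- function(tp, tn, fp, fn) {
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Two-state (buried/exposed) classification report
#'
#' Labels both RSA tracks with [two_state()] at the given percent threshold
#' and reports accuracy, MCC and the confusion counts. Exposed is the
#' positive class (MCC magnitude is class-symmetric; only the sign
#' convention depends on this choice).
#'
#' @inheritParams rsa_mae
#' @param threshold Burial threshold in percent.
#' @return List with `threshold`, `acc` (percent), `mcc` and counts
#'   `tp`, `tn`, `fp`, `fn` (class `two_state_report`).
#' @export
two_state_report <- function(pred, truth, threshold) {
  check_pair(pred, truth)
  p <- two_state(pred, threshold) == "exposed"
  t <- two_state(truth, threshold) == "exposed"
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  structure(list(threshold = threshold,
                 acc = 100 * (tp + tn) / length(p),
                 mcc = mcc_from_counts(tp, tn, fp, fn),
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "two_state_report")
}

#' @export
print.two_state_report <- function(x, ...) {
  cat(sprintf("two-state @ %g%%: ACC %.1f%%, MCC %.3f (TP %d TN %d FP %d FN %d)\n",
              x$threshold, x$acc, x$mcc, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Two-state performance over a threshold grid
#'
#' @inheritParams rsa_mae
#' @param thresholds Percent thresholds (default the standard grid
#'   5/10/20/25/30/40/50).
#' @return `data.frame` with one row per threshold: `threshold`, `acc`,
#'   `mcc`, `tp`, `tn`, `fp`, `fn`.
#' @export
two_state_table <- function(pred, truth,
                            thresholds = c(5, 10, 20, 25, 30, 40, 50)) {
  do.call(rbind, lapply(thresholds, function(th) {
    r <- two_state_report(pred, truth, th)
    data.frame(threshold = th, acc = r$acc, mcc = r$mcc, tp = r$tp,
               tn = r$tn, fp = r$fp, fn = r$fn)
  }))
}

#' Real-value evaluation report
#'
#' @inheritParams rsa_mae
#' @return List with `mae`, `rmse` (percent), `pcc`, `n`.
#' @export
real_value_report <- function(pred, truth) {
  list(mae = rsa_mae(pred, truth), rmse = rsa_rmse(pred, truth),
       pcc = rsa_pcc(pred, truth), n = length(pred))
}

#' Per-residue-type error profile
#'
#' Groups predictions by amino-acid type and reports, per type, the true and
#' predicted mean RSA, MAE, RMSE and the residue count. Types absent from
#' the data are omitted.
#'
#' @inheritParams rsa_mae
#' @param residues Character vector of residue letters, one per prediction.
#' @return `data.frame` with columns `residue`, `n`, `mean_true`,
#'   `mean_pred`, `mae`, `rmse`.
#' @export
per_residue_profile <- function(pred, truth, residues) {
  check_pair(pred, truth)
  stopifnot(length(residues) == length(pred))
  out <- lapply(sort(unique(residues)), function(aa) {
    i <- residues == aa
    data.frame(residue = aa, n = sum(i), mean_true = mean(truth[i]),
               mean_pred = mean(pred[i]), mae = rsa_mae(pred[i], truth[i]),
               rmse = rsa_rmse(pred[i], truth[i]))
  })
  do.call(rbind, out)
}
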