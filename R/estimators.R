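#' Per-step LUR weight
#'
#' The levelled unbiased risk estimator reweights the step-`j` inverse
#' probability sum by `w_j = N (N - s) / ((N - j)(N - j + 1))`. Summed over
#' `j = 1..s` these weights total exactly `s`, which is what makes the
#' estimator exactly unbiased for the full-pool mean loss. For `N >> s` every
#' `w_j` is close to 1.
#'
#' @param N Pool size.
#' @param s Current step (`s < N`).
#' @param j Step index or vector of indices, `1 <= j <= s`.
#' @return `w_j`, vectorized over `j`.
#' @export
lur_weight <- function(N, s, j) {
  if (s >= N) stop("lur_weight requires s < N")
  if (any(j < 1L | j > s)) stop("lur_weight requires 1 <= j <= s")
  N * (N - s) / ((N - j) * (N - j + 1))
}

#' LUR / AILUR estimate of a loss metric
#'
#' Computes `(1/(sN)) sum_j w_j sum_i delta^j_i L_i / pi_i`, where for a
#' record selected at step `t` the probability `pi` at its selection step is
#' its stored Poisson selection probability and `pi = 1` at every later step
#' (already-labeled records are carried with probability one). With
#' `weight_source = "true"` this is the LUR estimator; with `"estimated"` the
#' stored kernel-smoothed selection probabilities are used instead (AILUR).
#'
#' @param ledger A [label_ledger()] with completed steps `1..s`.
#' @param losses Numeric vector of length `N`; only entries of labeled
#'   records are read.
#' @param weight_source `"true"` or `"estimated"`.
#' @return The estimate.
#' @export
lur_estimate <- function(ledger, losses, weight_source = c("true", "estimated")) {
  weight_source <- match.arg(weight_source)
  s <- ledger$step
  if (s < 1L) stop("no completed sampling step")
  N <- length(ledger$delta)
  lab <- which(ledger$delta == 1L)
  pi_sel <- switch(weight_source, true = ledger$prob_true, estimated = ledger$prob_est)
  if (anyNA(pi_sel[lab]))
    stop("missing stored selection probability for a labeled record")
  w <- lur_weight(N, s, seq_len(s))
  # tail_w[t] = sum of w_j for j > t (steps where the record counts with pi = 1)
  tail_w <- rev(cumsum(rev(w))) - w
  t_i <- ledger$selection_step[lab]
  contrib <- w[t_i] * losses[lab] / pi_sel[lab] + tail_w[t_i] * losses[lab]
  sum(contrib) / (s * N)
}

#' AIIPW estimate of a loss metric
#'
#' The inverse-probability-weighted estimator
#' `(1/N) sum_i delta^s_i L_i / E-hat[delta^s_i | g(X_i)]`, using only the
#' current-step cumulative inclusion weights: unlike LUR/AILUR it does not
#' need the per-step probability history.
#'
#' @param ledger A [label_ledger()].
#' @param losses Numeric vector of length `N` (entries of labeled records read).
#' @param inclusion_weights Estimated `E[delta^s | g(X)]` per record.
#' @return The estimate.
#' @export
aiipw_estimate <- function(ledger, losses, inclusion_weights) {
  lab <- which(ledger$delta == 1L)
  if (length(lab) == 0L) stop("no labeled records")
  wts <- inclusion_weights[lab]
  if (any(!is.finite(wts) | wts <= 0))
    stop("inclusion weights must be positive for all labeled records")
  sum(losses[lab] / wts) / length(ledger$delta)
}

#' IPW estimate with true cumulative inclusion weights (testing oracle)
#'
#' Identical in form to [aiipw_estimate()] but fed the exact recursion
#' weights from [true_cumulative_inclusion()]; available only in simulation,
#' where it serves as the oracle the kernel-weighted AIIPW is checked
#' against.
#'
#' @inheritParams aiipw_estimate
#' @param true_inclusion Exact `E[delta^s | g(X)]` per record.
#' @return The estimate.
#' @export
ipw_oracle_estimate <- function(ledger, losses, true_inclusion) {
  aiipw_estimate(ledger, losses, true_inclusion)
}

#' AIIPW estimate of a ratio-form accuracy metric
#'
#' `[sum_i delta^s d1(g_i, Y_i) / E-hat_i] / [sum_i delta^s d2(g_i, Y_i) / E-hat_i]`
#' for the component functions of a [metric_spec()]. The ratio is invariant
#' to rescaling all weights by a constant.
#'
#' @param ledger A [label_ledger()].
#' @param spec A [metric_spec()].
#' @param scores Evaluated-model scores, length `N`.
#' @param labels Labels, length `N` (entries of labeled records read).
#' @param inclusion_weights `E-hat[delta^s | g(X)]` per record.
#' @return The weighted ratio estimate.
#' @export
aiipw_ratio_metric <- function(ledger, spec, scores, labels, inclusion_weights) {
  lab <- which(ledger$delta == 1L)
  if (length(lab) == 0L) stop("no labeled records")
  wts <- inclusion_weights[lab]
  if (any(!is.finite(wts) | wts <= 0))
    stop("inclusion weights must be positive for all labeled records")
  dd <- metric_components(spec, scores[lab], labels[lab])
  den <- sum(dd[, 2L] / wts)
  if (den <= 0)
    stop(sprintf("metric %s undefined at step %d: zero weighted d2 sum",
                 spec$name, ledger$step))
  sum(dd[, 1L] / wts) / den
}

#' Weighted AUC and AUPRC over the labeled records
#'
#' Sweeps risk cutoffs over the distinct labeled score values, plus a
#' sentinel below the minimum so every record eventually enters the curve
#' (with strict `>` indicators the top score itself yields the (0,0) corner),
#' and computes inverse-probability-weighted TPR, FPR and PPV at each cutoff. AUC is the trapezoidal area of TPR against FPR; AUPRC is the
#' trapezoidal area of PPV against TPR with points sorted by TPR, extending
#' the curve to TPR = 0 at the PPV of the highest-score point.
#'
#' @inheritParams aiipw_ratio_metric
#' @return Named numeric vector `c(auc = , auprc = )`.
#' @export
weighted_curve_metrics <- function(ledger, scores, labels, inclusion_weights) {
  lab <- which(ledger$delta == 1L)
  if (length(lab) == 0L) stop("no labeled records")
  y <- labels[lab]
  if (length(unique(y)) < 2L)
    stop("AUC/AUPRC undefined: only one class among labeled records")
  g <- scores[lab]
  w <- 1 / inclusion_weights[lab]
  cuts <- c(sort(unique(g), decreasing = TRUE), min(g) - 1)
  P <- sum(w * y)
  Nn <- sum(w * (1 - y))
  tpr <- fpr <- ppv <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    above <- g > cuts[k]
    tp <- sum(w[above] * y[above])
    fp <- sum(w[above] * (1 - y[above]))
    tpr[k] <- tp / P
    fpr[k] <- fp / Nn
    ppv[k] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1L) + utils::tail(tpr[ord], -1L)) / 2)
  keep <- !is.na(ppv)
  tpr_pr <- tpr[keep]; ppv_pr <- ppv[keep]
  # several cutoffs can share a TPR (ties, cutoffs past the extremes); the
  # attainable precision at that recall is the largest one
  best <- tapply(ppv_pr, tpr_pr, max)
  tpr_pr <- as.numeric(names(best)); ppv_pr <- as.numeric(best)
  # anchor at TPR = 0 with the PPV of the highest-score point
  first <- which.min(tpr_pr)
  tpr_pr <- c(0, tpr_pr)
  ppv_pr <- c(ppv_pr[first], ppv_pr)
  ord <- order(tpr_pr)
  auprc <- sum(diff(tpr_pr[ord]) *
                 (utils::head(ppv_pr[ord], -1L) + utils::tail(ppv_pr[ord], -1L)) / 2)
  c(auc = auc, auprc = auprc)
}
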