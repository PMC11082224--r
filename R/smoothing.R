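#' Kernel specification for weight smoothing
#'
#' Sampling weights are estimated by Nadaraya-Watson regression of selection
#' indicators on the evaluated model's score. The Gaussian kernel is the
#' default because its denominator is strictly positive everywhere; the
#' compact Epanechnikov kernel is available, with a global-mean fallback at
#' queries that receive zero kernel mass.
#'
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @param bandwidth Fixed positive bandwidth, or `NULL` to use `rule`.
#' @param rule Bandwidth rule when `bandwidth` is `NULL`: `"silverman"`
#'   (recomputed on the relevant support each step) or `"fixed"` (requires
#'   `bandwidth`).
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kernel = c("gaussian", "epanechnikov"),
                        bandwidth = NULL, rule = c("silverman", "fixed")) {
  kernel <- match.arg(kernel)
  rule <- match.arg(rule)
  if (rule == "fixed" && (is.null(bandwidth) || bandwidth <= 0))
    stop("rule = 'fixed' requires a positive bandwidth")
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive")
  structure(list(kernel = kernel, bandwidth = bandwidth, rule = rule),
            class = "kernel_spec")
}

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * m^(-1/5)` over the support values. If the
#' spread is degenerate (all values identical) a small constant bandwidth of
#' 0.05 is returned with a warning, which on (0,1)-scale scores behaves like a
#' moderately wide smoother.
#'
#' @param x Support covariate values (at least 2).
#' @return Positive bandwidth.
#' @export
silverman_bandwidth <- function(x) {
  if (length(x) < 2L) stop("silverman_bandwidth needs at least 2 values")
  spread <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (!is.finite(spread) || spread <= 0) {
    warning("degenerate support spread; using fallback bandwidth 0.05")
    return(0.05)
  }
  0.9 * spread * length(x)^(-1 / 5)
}

resolve_bandwidth <- function(spec, x) {
  if (!is.null(spec$bandwidth)) return(spec$bandwidth)
  silverman_bandwidth(x)
}

#' Nadaraya-Watson kernel regression
#'
#' Estimates `E[r | x = z]` at each query `z` as the kernel-weighted average
#' `sum_i r_i K_b(x_i - z) / sum_i K_b(x_i - z)`. For 0/1 responses the
#' estimate lies in `[0, 1]`.
#'
#' @param responses Numeric responses on the support.
#' @param covariate Scalar covariate per support record.
#' @param queries Points at which to evaluate the regression.
#' @param spec A [kernel_spec()].
#' @param self_exclude Leave-one-out evaluation: requires `queries` to be the
#'   support points themselves (in order); each query then omits its own
#'   kernel term from both sums. Used when the regression is evaluated at the
#'   support's own covariate values and the response of the queried record
#'   must not leak into its own weight estimate.
#' @return Estimate per query.
#' @export
nw_regress <- function(responses, covariate, queries, spec = kernel_spec(),
                       self_exclude = FALSE) {
  if (length(responses) == 0L) stop("nw_regress: empty support set")
  if (length(responses) != length(covariate))
    stop("responses and covariate must align")
  if (self_exclude && length(queries) != length(covariate))
    stop("self_exclude requires queries to be the support points themselves")
  if (length(responses) == 1L)  # single-point support: constant regression
    return(rep(as.numeric(responses), length(queries)))
  b <- resolve_bandwidth(spec, covariate)
  k <- if (spec$kernel == "gaussian") 1L else 2L
  out <- nw_smooth_cpp(as.numeric(covariate), as.numeric(responses),
                       as.numeric(queries), b, k, self_exclude)
  if (anyNA(out)) {
    warning("zero kernel mass at some queries; substituting the support mean")
    out[is.na(out)] <- mean(responses)
  }
  out
}

#' Kernel estimate of the per-step selection probability (AILUR weights)
#'
#' After step `s` completes, regresses the new-selection indicator
#' `delta^s (1 - delta^{s-1})` on the current step's conditioning score over
#' the previously-unlabeled support, and evaluates at each previously-
#' unlabeled record's own score. Estimates are clipped to `[floor, 1]`.
#'
#' @param ledger A [label_ledger()] with step `s` already recorded.
#' @param step_scores Scalar conditioning score per record (all `N`): the
#'   plug-in model score that drove this step's sampling.
#' @param spec A [kernel_spec()].
#' @param floor Lower clip for the estimated probabilities.
#' @param self_exclude Passed to [nw_regress()].
#' @param calibrate Rescale weights so the weighted selected count matches
#'   the support size.
#' @return Numeric vector of length `N`: estimated selection probabilities
#'   for previously-unlabeled records, `NA` for records labeled before this
#'   step.
#' @export
estimate_step_selection_prob <- function(ledger, step_scores,
                                         spec = kernel_spec(), floor = 1e-3,
                                         self_exclude = FALSE,
                                         calibrate = TRUE) {
  s <- ledger$step
  if (s < 1L) stop("no completed sampling step in the ledger")
  prev_unlab <- ledger$delta == 0L |
    (!is.na(ledger$selection_step) & ledger$selection_step == s)
  if (!any(prev_unlab)) stop("no previously-unlabeled records at this step")
  newly <- as.numeric(!is.na(ledger$selection_step) &
                        ledger$selection_step == s)[prev_unlab]
  x <- step_scores[prev_unlab]
  est <- nw_regress(newly, x, x, spec, self_exclude = self_exclude)
  est <- pmin(1, pmax(floor, est))
  if (calibrate && any(newly == 1)) {
    est <- est * sum(1 / est[newly == 1]) / length(x)
    est <- pmin(1, pmax(floor, est))
  }
  out <- rep(NA_real_, length(ledger$delta))
  out[prev_unlab] <- est
  out
}

#' Kernel estimate of the cumulative inclusion probability (AIIPW weights)
#'
#' Regresses the cumulative inclusion indicator `delta^s` on the original
#' model score `g(X)` over all `N` records and evaluates at every record's
#' own score. Valid whenever all historical sampling probabilities were
#' functions of `g`. Estimates are clipped to `[floor, 1]`.
#'
#' With `calibrate = TRUE` (the default) the clipped estimates are rescaled
#' so that the inverse-weighted count of labeled records equals the pool
#' size `N` (the Hajek normalization of the inclusion weights).
#'
#' @param ledger A [label_ledger()] with at least one labeled record.
#' @param base_scores Scalar conditioning score per record derived from the
#'   original evaluated model (the binary score itself, or the expected-loss
#'   score for multiclass models).
#' @param spec A [kernel_spec()].
#' @param floor Lower clip.
#' @param self_exclude Passed to [nw_regress()].
#' @param calibrate Hajek-normalize the inclusion weights.
#' @return Estimated `E[delta^s | g(X)]` per record (length `N`).
#' @export
estimate_cumulative_inclusion <- function(ledger, base_scores,
                                          spec = kernel_spec(), floor = 1e-3,
                                          self_exclude = FALSE,
                                          calibrate = TRUE) {
  if (sum(ledger$delta) == 0L) stop("no labeled records yet")
  est <- nw_regress(as.numeric(ledger$delta), base_scores, base_scores, spec,
                    self_exclude = self_exclude)
  est <- pmin(1, pmax(floor, est))
  if (calibrate) {
    lab <- ledger$delta == 1L
    est <- est * sum(1 / est[lab]) / length(est)
    est <- pmin(1, pmax(floor, est))
  }
  est
}

#' Exact cumulative inclusion probability by recursion (testing oracle)
#'
#' Given each completed step's selection-probability map evaluated at every
#' record, computes `E[delta^s | g(X)]` by the recursion
#' `E[delta^1|g] = P(delta^1 = 1 | g)` and, for `s > 1`,
#' `E[delta^s|g] = E[delta^{s-1}|g] + P(delta^s=1|g) * prod_{j<s} (1 - P(delta^j=1|g))`.
#'
#' @param step_probs List of numeric vectors, one per completed step, each of
#'   length `N`: the step's conditional selection probability evaluated at
#'   every record's score.
#' @return `E[delta^s | g(X)]` per record, in (0, 1].
#' @export
true_cumulative_inclusion <- function(step_probs) {
  if (length(step_probs) == 0L) stop("no step probability functions supplied")
  if (any(vapply(step_probs, is.null, logical(1L))))
    stop("missing step probability function")
  e_prev <- step_probs[[1L]]
  surv <- 1 - step_probs[[1L]]
  if (length(step_probs) > 1L) {
    for (s in 2L:length(step_probs)) {
      p_s <- step_probs[[s]]
      e_prev <- e_prev + p_s * surv
      surv <- surv * (1 - p_s)
    }
  }
  e_prev
}
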