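#' Expected cross-entropy acquisition score
#'
#' Entropy sampling selects records in proportion to the expected
#' cross-entropy loss of the evaluated model `g` under plug-in outcome
#' probabilities `p`: for binary outcomes
#' `-[p log g + (1-p) log(1-g)]`, and for multiclass
#' `-sum_c p_c log g_c`. Larger expected loss means the record is more likely
#' to be selected for labeling. The plug-in `p` may be the evaluated model
#' itself ("Ori"), an auxiliary probability model ("RF" slot), or the
#' recalibrated model ("Rec").
#'
#' @param scores Evaluated-model scores `g` (vector or matrix).
#' @param reference_probs Plug-in outcome probabilities, same shape.
#' @return Nonnegative acquisition score per record.
#' @export
expected_loss_score <- function(scores, reference_probs) {
  if (is.matrix(scores)) {
    if (!is.matrix(reference_probs) ||
        !all(dim(scores) == dim(reference_probs)))
      stop("scores and reference_probs must have the same shape")
    if (any(scores <= 0 | scores >= 1))
      stop("scores must lie strictly inside (0, 1)")
    -rowSums(reference_probs * log(scores))
  } else {
    if (length(scores) != length(reference_probs))
      stop("scores and reference_probs must have the same length")
    if (any(scores <= 0 | scores >= 1))
      stop("scores must lie strictly inside (0, 1)")
    -(reference_probs * log(scores) + (1 - reference_probs) * log(1 - scores))
  }
}

#' Normalize acquisition scores to Poisson sampling probabilities
#'
#' Scales nonnegative scores so the probabilities sum to the expected
#' subsample size `n_s`: `p_i = n_s * score_i / sum(score)`. Any `p_i > 1` is
#' capped at 1 and the residual expected count is redistributed
#' proportionally over the uncapped records, iterating until no cap binds.
#' Values below the floor `eps` are then raised to `eps` (the excess expected
#' count is not rebalanced). The floor guarantees `0 < p <= 1` as the
#' weighting theory requires and bounds the variance of inverse-probability
#' weights.
#'
#' @param raw_scores Nonnegative acquisition scores of the unlabeled records.
#' @param n_s Expected number of new labels this step.
#' @param floor Probability floor `eps`.
#' @return Probability vector over the unlabeled records, with attribute
#'   `"lambda"` holding the final proportionality constant of the capped map
#'   `p(raw) = min(1, lambda * raw)` (used by the inclusion-probability
#'   oracle).
#' @export
normalize_to_probabilities <- function(raw_scores, n_s, floor = 1e-3) {
  m <- length(raw_scores)
  if (n_s > m) stop("expected subsample size exceeds the unlabeled pool")
  if (any(raw_scores < 0)) stop("acquisition scores must be nonnegative")
  if (all(raw_scores == 0)) {
    warning("all acquisition scores are zero; falling back to uniform sampling")
    p <- rep(n_s / m, m)
    attr(p, "lambda") <- NA_real_
    return(p)
  }
  capped <- rep(FALSE, m)
  lambda <- n_s / sum(raw_scores)
  repeat {
    p <- ifelse(capped, 1, lambda * raw_scores)
    over <- !capped & p > 1
    if (!any(over)) break
    capped <- capped | over
    resid <- n_s - sum(capped)
    free_mass <- sum(raw_scores[!capped])
    if (resid <= 0 || free_mass <= 0) {
      p <- ifelse(capped, 1, 0)
      break
    }
    lambda <- resid / free_mass
  }
  p <- pmin(p, 1)
  p <- pmax(p, floor)
  attr(p, "lambda") <- lambda
  p
}

#' Uniform sampling probabilities
#'
#' @param m Number of unlabeled records.
#' @param n_s Expected subsample size (`n_s <= m`).
#' @return Constant probability vector `n_s / m`.
#' @export
uniform_probabilities <- function(m, n_s) {
  if (n_s > m) stop("expected subsample size exceeds the unlabeled pool")
  rep(n_s / m, m)
}

#' Poisson draw of new selections
#'
#' Independent Bernoulli selection of each unlabeled record with its own
#' probability; the realized subsample size is random with expectation
#' `sum(probs)`.
#'
#' @param probs Probability per unlabeled record, each in (0, 1].
#' @return Logical vector of new selections.
#' @export
poisson_draw <- function(probs) {
  if (any(probs <= 0 | probs > 1)) stop("probabilities must lie in (0, 1]")
  stats::rbinom(length(probs), 1L, probs) == 1L
}

#' Sequential draw without replacement (optional scheme)
#'
#' Draws exactly `n_s` distinct records, sequentially with per-draw
#' probabilities proportional to the raw scores. The first-order inclusion
#' probability stored alongside is the approximation
#' `min(1, n_s * score / sum(score))`; the exact joint-inclusion computation
#' for sequential proportional draws is deliberately not attempted.
#'
#' @param raw_scores Nonnegative scores of the unlabeled records.
#' @param n_s Number of records to draw.
#' @param floor Floor applied to the stored inclusion approximation.
#' @return List with `selected` (logical vector) and `inclusion_prob`
#'   (approximate first-order inclusion probabilities, full vector).
#' @export
swr_draw <- function(raw_scores, n_s, floor = 1e-3) {
  m <- length(raw_scores)
  if (n_s > m) stop("cannot draw more records than remain unlabeled")
  if (all(raw_scores == 0)) raw_scores <- rep(1, m)
  idx <- sample.int(m, n_s, replace = FALSE, prob = raw_scores)
  selected <- rep(FALSE, m)
  selected[idx] <- TRUE
  incl <- pmax(floor, pmin(1, n_s * raw_scores / sum(raw_scores)))
  list(selected = selected, inclusion_prob = incl)
}
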