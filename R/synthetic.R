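#' Specification of a synthetic evaluation pool
#'
#' Generates test pools with known ground truth so estimators and the
#' recalibration step can be checked against a full-data benchmark. The data
#' emulate the active-testing setting: the training set of the evaluated
#' model is inaccessible, only its scores are visible, and the model may be
#' deliberately miscalibrated.
#'
#' Covariates are standard normal. For binary outcomes the true conditional
#' probability is `plogis(intercept + X beta)` and the evaluated model's
#' score is `plogis(a + b * logit(p_true))`: `(a, b) = (0, 1)` is perfect
#' calibration, `b < 1` shrinks logits toward zero (scores too close to
#' 1/2). For multiclass outcomes the truth is a softmax over class-specific
#' linear scores and the evaluated model applies a shared temperature
#' distortion `softmax(b * eta)`.
#'
#' @param n Number of records.
#' @param p Number of covariates.
#' @param outcome `"binary"` or `"multiclass"`.
#' @param classes Number of classes for multiclass outcomes.
#' @param beta Coefficients of the true model: length-`p` vector (binary) or
#'   `classes x p` matrix (multiclass). Defaults: `c(0.8, -0.8, 0.5)`
#'   recycled to `p` for binary; `1.5 * cos(c * j)` for multiclass.
#' @param intercept True-model intercept (binary only).
#' @param miscalibration `c(a, b)` of the evaluated model's score map.
#' @param seed Integer seed for reproducible generation.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n = 2000, p = 3,
                           outcome = c("binary", "multiclass"), classes = 3,
                           beta = NULL, intercept = 0,
                           miscalibration = c(0, 0.6), seed = NULL) {
  outcome <- match.arg(outcome)
  if (n < 1L || p < 1L) stop("invalid synthetic pool dimensions")
  if (outcome == "multiclass" && classes < 2L)
    stop("multiclass pools need at least 2 classes")
  if (is.null(beta)) {
    beta <- if (outcome == "binary") rep_len(c(0.8, -0.8, 0.5), p)
            else outer(seq_len(classes), seq_len(p), function(i, j) 1.5 * cos(i * j))
  }
  if (outcome == "binary" && length(beta) != p)
    stop("binary beta must have length p")
  if (outcome == "multiclass" &&
      (!is.matrix(beta) || any(dim(beta) != c(classes, p))))
    stop("multiclass beta must be a classes x p matrix")
  if (length(miscalibration) != 2L)
    stop("miscalibration must be c(a, b)")
  structure(list(n = n, p = p, outcome = outcome, classes = classes,
                 beta = beta, intercept = intercept,
                 miscalibration = miscalibration, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic test pool
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled [test_pool()] with `true_probs` retained for oracle
#'   checks.
#' @examples
#' pool <- generate_pool(synthetic_spec(n = 100, seed = 1))
#' mean(all_labels(pool))
#' @export
generate_pool <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p)
  a <- spec$miscalibration[1L]
  b <- spec$miscalibration[2L]
  if (spec$outcome == "binary") {
    p_true <- stats::plogis(spec$intercept + drop(X %*% spec$beta))
    y <- stats::rbinom(spec$n, 1L, p_true)
    score <- stats::plogis(a + b * stats::qlogis(p_true))
  } else {
    eta <- X %*% t(spec$beta)
    p_true <- exp(eta - apply(eta, 1L, max))
    p_true <- p_true / rowSums(p_true)
    y <- vapply(seq_len(spec$n),
                function(i) sample.int(spec$classes, 1L, prob = p_true[i, ]),
                integer(1L))
    sc <- exp(b * eta - apply(b * eta, 1L, max))
    score <- sc / rowSums(sc)
  }
  test_pool(score, labels = y, covariates = X, true_probs = p_true)
}

#' Deterministic 8-record fixture pool
#'
#' A hard-coded pool with scores spanning (0.1, 0.9) and both classes
#' present, together with its hand-computed benchmark values, used in unit
#' tests. The scores pair up so that the mean cross-entropy is exactly
#' `-log(0.6)`.
#'
#' @return List with `pool` (a [test_pool()]) and `benchmark` (named list
#'   with `cross_entropy`, `TPR`, `PPV`, `F1` at cutoff 0.5).
#' @export
make_fixture <- function() {
  pool <- test_pool(scores = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9),
                    labels = c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L))
  list(pool = pool,
       benchmark = list(cross_entropy = 0.5108256237659907,
                        TPR = 0.75, PPV = 0.75, F1 = 0.375))
}
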