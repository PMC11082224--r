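#' Solve the weighted recalibration estimating equation
#'
#' Fits the one-parameter recalibration `h(theta * g(X))` of the evaluated
#' model by solving
#' `sum_i delta^s_i g_i [Y_i - h(theta g_i)] / E-hat_i = 0`
#' over the labeled records. With the logistic link
#' `h(u) = 1 / (1 + exp(-u))` the residual is continuous and strictly
#' decreasing in `theta` (scores are positive), so the root is unique
#' whenever it exists and is found by bracketed root finding on
#' `[-theta_max, theta_max]` to tolerance `1e-10`. When no finite root exists
#' (e.g. all labeled outcomes equal), `theta` is capped at the boundary with
#' `fallback_used` set.
#'
#' The recalibration acts on the probability-scale score `theta * g(X)` by
#' default; set `on_logit_scale = TRUE` to recalibrate `theta * logit(g)`
#' instead (a non-default variant).
#'
#' @param labels Labeled outcomes (0/1).
#' @param scores Evaluated-model scores `g` of the labeled records.
#' @param weights Cumulative inclusion weights `E-hat` of the labeled records.
#' @param link `"logistic"` or `"linear"` (`h(u) = u`, closed-form solution).
#' @param theta_max Cap for the parameter search.
#' @param on_logit_scale Recalibrate on the logit of `g` instead of `g`.
#' @return An object of class `"recalibration_fit"` with fields `theta`,
#'   `link`, `converged`, `fallback_used`, `residual`, `on_logit_scale`.
#' @export
solve_recalibration <- function(labels, scores, weights = rep(1, length(labels)),
                                link = c("logistic", "linear"),
                                theta_max = 20, on_logit_scale = FALSE) {
  link <- match.arg(link)
  if (length(labels) == 0L) stop("no labeled records to recalibrate on")
  if (any(weights <= 0)) stop("inclusion weights must be positive")
  u <- if (on_logit_scale) stats::qlogis(scores) else scores
  fit <- list(link = link, on_logit_scale = on_logit_scale,
              converged = FALSE, fallback_used = FALSE)
  if (link == "linear") {
    denom <- sum(u^2 / weights)
    if (denom <= 0) stop("degenerate linear recalibration: zero score mass")
    fit$theta <- sum(u * labels / weights) / denom
    fit$residual <- sum(u * (labels - fit$theta * u) / weights)
    fit$converged <- abs(fit$residual) <= 1e-8
    class(fit) <- "recalibration_fit"
    return(fit)
  }
  resid <- function(theta) sum(u * (labels - stats::plogis(theta * u)) / weights)
  r_lo <- resid(-theta_max)
  r_hi <- resid(theta_max)
  if (r_lo < 0 || r_hi > 0 || r_lo == r_hi) {
    # residual is decreasing; no sign change within the cap -> boundary fallback
    fit$theta <- if (abs(r_hi) < abs(r_lo)) theta_max else -theta_max
    fit$residual <- resid(fit$theta)
    fit$fallback_used <- TRUE
    class(fit) <- "recalibration_fit"
    return(fit)
  }
  sol <- stats::uniroot(resid, lower = -theta_max, upper = theta_max,
                        tol = 1e-10)
  fit$theta <- sol$root
  fit$residual <- resid(fit$theta)
  fit$converged <- abs(fit$residual) <= 1e-8
  class(fit) <- "recalibration_fit"
  fit
}

#' @export
print.recalibration_fit <- function(x, ...) {
  cat(sprintf("Recalibration fit: theta = %.6f (%s link%s)%s\n",
              x$theta, x$link,
              if (x$on_logit_scale) ", logit scale" else "",
              if (x$fallback_used) " [boundary fallback]" else ""))
  invisible(x)
}

#' Recalibrated outcome probabilities
#'
#' Maps scores through the fitted link, `h(theta * g)`, clipping into
#' `(eps, 1 - eps)`. These probabilities are the "Rec" plug-in feeding
#' [expected_loss_score()] when updating the sampling probabilities.
#'
#' @param fit A [solve_recalibration()] fit.
#' @param scores Evaluated-model scores `g` (all records).
#' @param eps Clipping margin.
#' @return Recalibrated probability per record.
#' @export
recalibrated_probs <- function(fit, scores, eps = 1e-3) {
  u <- if (fit$on_logit_scale) stats::qlogis(scores) else scores
  p <- switch(fit$link,
              logistic = stats::plogis(fit$theta * u),
              linear = fit$theta * u)
  pmin(1 - eps, pmax(eps, p))
}

#' Multiclass recalibration by one-vs-rest (synthetic stand-in)
#'
#' Applies the scalar recalibration equation separately to each class score
#' against the indicator of that class, then renormalizes the recalibrated
#' probabilities to the simplex. This one-vs-rest construction is a
#' documented stand-in for a joint multinomial recalibration; with `C = 2`
#' it delegates to the binary path on the class-1 score (the complement gives
#' class 2). A class absent from the labeled data keeps `theta = 1` for its
#' score, with a warning.
#'
#' @param labels Labeled class indices (1..C).
#' @param score_matrix Score matrix of the labeled records (rows) by class
#'   (columns) used for fitting.
#' @param weights Inclusion weights of the labeled records.
#' @param all_scores Score matrix of all records to recalibrate (defaults to
#'   `score_matrix`).
#' @param eps Clipping margin before renormalization.
#' @param theta_max Parameter cap passed through.
#' @return Recalibrated probability matrix over `all_scores` rows, with
#'   attribute `"theta"` (per-class parameters).
#' @export
multiclass_recalibrated_probs <- function(labels, score_matrix,
                                          weights = rep(1, length(labels)),
                                          all_scores = score_matrix,
                                          eps = 1e-3, theta_max = 20) {
  C <- ncol(score_matrix)
  if (length(unique(labels)) < 2L)
    stop("multiclass recalibration needs at least 2 observed classes")
  if (C == 2L) {
    fit <- solve_recalibration(as.integer(labels == 1L), score_matrix[, 1L],
                               weights, link = "logistic", theta_max = theta_max)
    p1 <- recalibrated_probs(fit, all_scores[, 1L], eps)
    out <- cbind(p1, 1 - p1)
    attr(out, "theta") <- c(fit$theta, NA_real_)
    return(out)
  }
  theta <- rep(1, C)
  out <- matrix(NA_real_, nrow(all_scores), C)
  for (cc in seq_len(C)) {
    y_c <- as.integer(labels == cc)
    if (sum(y_c) == 0L) {
      warning(sprintf("class %d absent from labeled data; keeping theta = 1", cc))
    } else {
      fit <- solve_recalibration(y_c, score_matrix[, cc], weights,
                                 link = "logistic", theta_max = theta_max)
      theta[cc] <- fit$theta
    }
    out[, cc] <- pmin(1 - eps, pmax(eps, stats::plogis(theta[cc] * all_scores[, cc])))
  }
  out <- out / rowSums(out)
  attr(out, "theta") <- theta
  out
}
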