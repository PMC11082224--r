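step_seed <- function(seed, rep_id, step) {
  as.integer((as.numeric(seed) * 2099 + rep_id * 65537 + step * 101) %% 2147483647)
}

metric_id <- function(m) {
  if (inherits(m, "loss_spec")) m$name
  else if (inherits(m, "metric_spec")) m$name
  else if (is.character(m) && m %in% c("auc", "auprc")) m
  else stop("metrics must be loss_spec, metric_spec, 'auc' or 'auprc'")
}

#' Run one repetition of the active-testing loop
#'
#' Orchestrates the sequential evaluation of a pre-trained model on an
#' unlabeled test pool. At each step `s = 1..steps`: (1) sampling
#' probabilities over the remaining unlabeled records are built from the
#' expected cross-entropy loss of the evaluated model under the current
#' plug-in outcome probabilities; (2) a new batch is drawn (Poisson scheme by
#' default); (3) kernel-smoothed weight estimates are refreshed; (4) every
#' requested estimator/metric is computed on the accumulated labeled data;
#' (5) if `prob_update = "Rec"`, the recalibration equation is refit and the
#' plug-in probabilities updated for the next step.
#'
#' Plug-in schemes: `"Ori"` keeps the evaluated model's own scores, `"Rec"`
#' recalibrates them on the accumulated labels, `"RF"` delegates to the
#' pluggable `prob_model` (fit on labeled covariates), and `"Uniform"` uses
#' constant probabilities. The AIIPW estimator (and all weighted ratio/curve
#' metrics) require the sampling probabilities to be a function of the
#' evaluated model's score, so they are unavailable under `"RF"`.
#'
#' @param pool A [test_pool()] with labels behind the oracle.
#' @param steps Number of sampling steps `S`.
#' @param n_s Expected new-label count per step.
#' @param scheme `"poisson"` (default) or `"swr"` (sequential without
#'   replacement, with approximate first-order inclusion probabilities).
#' @param prob_update `"Ori"`, `"Rec"`, `"RF"` or `"Uniform"`.
#' @param estimators Subset of `c("LUR", "AILUR", "AIIPW", "IPW_oracle")`.
#'   `"IPW_oracle"` uses the exact inclusion-probability recursion and is for
#'   simulation checks only.
#' @param metrics List of [loss_spec()] / [metric_spec()] objects and/or the
#'   strings `"auc"`, `"auprc"`.
#' @param kernel A [kernel_spec()].
#' @param prob_floor Floor `eps` for sampling probabilities and estimated
#'   weights.
#' @param self_exclude,calibrate Options of the kernel weight estimators
#'   (see [estimate_step_selection_prob()] and
#'   [estimate_cumulative_inclusion()]).
#' @param link,theta_max Passed to [solve_recalibration()] for `"Rec"`.
#' @param prob_model For `"RF"`: `function(x_labeled, y_labeled, x_all)`
#'   returning outcome probabilities for all records; defaults to a random
#'   forest when the randomForest package is available.
#' @param keep_history Keep each step's full selection-probability map (also
#'   turned on automatically when `"IPW_oracle"` is requested).
#' @param seed Integer seed; per-step substreams are derived
#'   deterministically from `(seed, rep_id, step)` so a fixed seed gives a
#'   bit-identical trace.
#' @param rep_id Repetition index used in seed derivation.
#' @return An object of class `"active_test"` with fields `estimates` (data
#'   frame `step`, `estimator`, `metric`, `value`), `ledger`, `fits`,
#'   `history`, `config`.
#' @examples
#' pool <- generate_pool(synthetic_spec(n = 400, seed = 7))
#' fit <- active_test(pool, steps = 2, n_s = 40, seed = 11)
#' coef(fit)
#' @export
active_test <- function(pool, steps = 3, n_s = 100,
                        scheme = c("poisson", "swr"),
                        prob_update = c("Ori", "Rec", "RF", "Uniform"),
                        estimators = c("LUR", "AILUR", "AIIPW"),
                        metrics = list(loss_spec("cross_entropy")),
                        kernel = kernel_spec(), prob_floor = 1e-3,
                        self_exclude = FALSE, calibrate = TRUE,
                        link = "logistic", theta_max = 20,
                        prob_model = NULL, keep_history = FALSE,
                        seed = NULL, rep_id = 1L) {
  scheme <- match.arg(scheme)
  prob_update <- match.arg(prob_update)
  estimators <- match.arg(estimators,
                          c("LUR", "AILUR", "AIIPW", "IPW_oracle"),
                          several.ok = TRUE)
  g <- pool$scores
  N <- pool$n
  binary <- !is.matrix(g)
  if (steps * n_s > N)
    stop("steps * n_s exceeds the pool size")
  metric_ids <- vapply(metrics, metric_id, character(1L))
  has_ratio <- any(vapply(metrics, inherits, logical(1L), "metric_spec"))
  wants_auc <- "auc" %in% metric_ids
  wants_auprc <- "auprc" %in% metric_ids
  if (!binary && (has_ratio || wants_auc || wants_auprc))
    stop("ratio and curve metrics are defined for binary pools only")
  need_ehat <- "AIIPW" %in% estimators || has_ratio || wants_auc ||
    wants_auprc || prob_update == "Rec"
  need_oracle <- "IPW_oracle" %in% estimators
  if ((("AIIPW" %in% estimators) || has_ratio || wants_auc || wants_auprc) &&
      prob_update == "RF")
    stop("AIIPW-weighted quantities require prob_update in {Ori, Rec, Uniform}: ",
         "RF sampling probabilities are not a function of the evaluated model")
  if (prob_update == "RF") {
    if (is.null(prob_model)) prob_model <- default_rf_prob_model
    if (is.null(pool$covariates))
      stop("prob_update = 'RF' needs pool covariates")
  }
  keep_history <- keep_history || need_oracle

  cond_base <- if (binary) g else expected_loss_score(g, g)
  plug <- g
  ledger <- label_ledger(N)
  history <- vector("list", steps)
  fits <- vector("list", steps)
  rows_step <- integer(0); rows_est <- character(0)
  rows_metric <- character(0); rows_value <- numeric(0)
  add_row <- function(s, e, m, v) {
    rows_step[[length(rows_step) + 1L]] <<- s
    rows_est[[length(rows_est) + 1L]] <<- e
    rows_metric[[length(rows_metric) + 1L]] <<- m
    rows_value[[length(rows_value) + 1L]] <<- v
  }

  for (s in seq_len(steps)) {
    unlab <- which(ledger$delta == 0L)
    m <- length(unlab)
    if (m < n_s) {
      warning(sprintf("pool exhausted before step %d; stopping early", s))
      break
    }
    uniform_step <- prob_update == "Uniform"
    raw_all <- if (uniform_step) rep(1, N) else expected_loss_score(g, plug)
    if (!is.null(seed)) set.seed(step_seed(seed, rep_id, s))
    if (scheme == "poisson") {
      probs <- if (uniform_step) uniform_probabilities(m, n_s)
               else normalize_to_probabilities(raw_all[unlab], n_s, prob_floor)
      sel_local <- which(poisson_draw(probs))
      p_sel <- probs[sel_local]
      lambda <- if (uniform_step) NA_real_ else attr(probs, "lambda")
    } else {
      d <- swr_draw(raw_all[unlab], n_s, prob_floor)
      sel_local <- which(d$selected)
      p_sel <- d$inclusion_prob[sel_local]
      lambda <- n_s / sum(raw_all[unlab])
    }
    sel <- unlab[sel_local]
    ledger <- ledger_update(ledger, sel, p_sel)
    if (keep_history) {
      history[[s]] <- if (uniform_step || is.na(lambda)) rep(n_s / m, N)
                      else pmin(1, pmax(prob_floor, lambda * raw_all))
    }

    cond_step <- if (uniform_step) cond_base
                 else if (binary) as.numeric(plug) else raw_all
    if ("AILUR" %in% estimators) {
      est <- estimate_step_selection_prob(ledger, cond_step, kernel, prob_floor,
                                          self_exclude = self_exclude,
                                          calibrate = calibrate)
      ledger$prob_est[sel] <- est[sel]
    }

    lab <- which(ledger$delta == 1L)
    y <- oracle_labels(pool, ledger, lab)
    labels_full <- rep(NA_integer_, N)
    labels_full[lab] <- y
    ehat <- if (need_ehat)
      estimate_cumulative_inclusion(ledger, cond_base, kernel, prob_floor,
                                    self_exclude = self_exclude,
                                    calibrate = calibrate)
    etrue <- if (need_oracle) true_cumulative_inclusion(history[seq_len(s)])

    curve_vals <- NULL
    for (k in seq_along(metrics)) {
      mt <- metrics[[k]]
      id <- metric_ids[k]
      if (inherits(mt, "loss_spec")) {
        losses_full <- rep(NA_real_, N)
        sc_lab <- if (binary) g[lab] else g[lab, , drop = FALSE]
        losses_full[lab] <- pointwise_loss(mt, sc_lab, y)
        for (e in estimators) {
          v <- switch(e,
                      LUR = lur_estimate(ledger, losses_full, "true"),
                      AILUR = lur_estimate(ledger, losses_full, "estimated"),
                      AIIPW = aiipw_estimate(ledger, losses_full, ehat),
                      IPW_oracle = ipw_oracle_estimate(ledger, losses_full, etrue))
          add_row(s, e, id, v)
        }
      } else if (inherits(mt, "metric_spec")) {
        add_row(s, "AIIPW", id,
                aiipw_ratio_metric(ledger, mt, g, labels_full, ehat))
        if (need_oracle)
          add_row(s, "IPW_oracle", id,
                  aiipw_ratio_metric(ledger, mt, g, labels_full, etrue))
      } else {
        if (is.null(curve_vals))
          curve_vals <- weighted_curve_metrics(ledger, g, labels_full, ehat)
        add_row(s, "AIIPW", id, unname(curve_vals[id]))
      }
    }

    if (prob_update == "Rec") {
      if (binary) {
        fit <- solve_recalibration(y, g[lab], ehat[lab], link = link,
                                   theta_max = theta_max)
        plug <- recalibrated_probs(fit, g, prob_floor)
      } else {
        plug <- multiclass_recalibrated_probs(y, g[lab, , drop = FALSE],
                                              ehat[lab], all_scores = g,
                                              eps = prob_floor,
                                              theta_max = theta_max)
        fit <- attr(plug, "theta")
      }
      fits[[s]] <- fit
    } else if (prob_update == "RF") {
      plug <- prob_model(pool$covariates[lab, , drop = FALSE], y,
                         pool$covariates)
      plug <- if (is.matrix(plug)) {
        plug <- pmin(1 - prob_floor, pmax(prob_floor, plug))
        plug / rowSums(plug)
      } else pmin(1 - prob_floor, pmax(prob_floor, plug))
    }
  }

  structure(
    list(estimates = data.frame(step = rows_step, estimator = rows_est,
                                metric = rows_metric, value = rows_value,
                                stringsAsFactors = FALSE),
         ledger = ledger, fits = fits,
         history = if (keep_history) history,
         config = list(steps = steps, n_s = n_s, scheme = scheme,
                       prob_update = prob_update, estimators = estimators,
                       metrics = metric_ids, prob_floor = prob_floor,
                       seed = seed, rep_id = rep_id)),
    class = "active_test")
}

# default pluggable auxiliary probability model for the "RF" slot
default_rf_prob_model <- function(x_labeled, y_labeled, x_all) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("the default RF probability model needs the randomForest package; ",
         "supply prob_model= instead")
  yf <- factor(y_labeled)
  rf <- randomForest::randomForest(x_labeled, yf)
  pr <- stats::predict(rf, x_all, type = "prob")
  if (nlevels(yf) == 2L && all(levels(yf) %in% c("0", "1"))) pr[, "1"] else pr
}

#' @export
print.active_test <- function(x, ...) {
  cat(sprintf("Active testing run: %d step(s), %d labeled of %d records (%s, %s)\n",
              x$ledger$step, sum(x$ledger$delta), length(x$ledger$delta),
              x$config$scheme, x$config$prob_update))
  cat("Final-step estimates:\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.active_test <- function(object, ...) {
  est <- object$estimates
  fin <- est[est$step == max(est$step), ]
  stats::setNames(fin$value, paste(fin$estimator, fin$metric, sep = "."))
}

#' @export
summary.active_test <- function(object, ...) {
  out <- list(config = object$config,
              n_labeled = sum(object$ledger$delta),
              new_counts = object$ledger$new_counts,
              estimates = object$estimates)
  class(out) <- "summary.active_test"
  out
}

#' @export
print.summary.active_test <- function(x, ...) {
  cat(sprintf("Active testing: %s sampling, plug-in '%s'\n",
              x$config$scheme, x$config$prob_update))
  cat(sprintf("Labeled %d records over %d step(s); per-step new labels: %s\n",
              x$n_labeled, length(x$new_counts),
              paste(x$new_counts, collapse = ", ")))
  wide <- stats::reshape(x$estimates, idvar = c("step", "metric"),
                         timevar = "estimator", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' @export
plot.active_test <- function(x, metric = x$config$metrics[1L], benchmark = NULL, ...) {
  est <- x$estimates[x$estimates$metric == metric, ]
  if (nrow(est) == 0L) stop("no estimates for metric ", metric)
  ests <- unique(est$estimator)
  steps <- sort(unique(est$step))
  mat <- sapply(ests, function(e) est$value[est$estimator == e][order(est$step[est$estimator == e])])
  graphics::matplot(steps, mat, type = "b", pch = 19, lty = 1,
                    xlab = "sampling step", ylab = metric, ...)
  if (!is.null(benchmark)) graphics::abline(h = benchmark, lty = 2)
  graphics::legend("topright", legend = ests, col = seq_along(ests),
                   pch = 19, bty = "n")
  invisible(x)
}
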