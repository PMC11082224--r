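#' Loss specification for loss-based performance metrics
#'
#' The evaluation target is the population mean loss `E[L{g(X), Y}]` of the
#' evaluated model `g`. Supported pointwise losses are the cross-entropy and
#' the squared error.
#'
#' @param name One of `"cross_entropy"`, `"squared_error"`.
#' @return An object of class `"loss_spec"`.
#' @export
loss_spec <- function(name = c("cross_entropy", "squared_error")) {
  name <- match.arg(name)
  structure(list(name = name), class = "loss_spec")
}

#' Pointwise cross-entropy loss
#'
#' For a binary score `g` and label `y` returns `-[y log g + (1-y) log(1-g)]`;
#' for a multiclass score matrix and class label `y` returns `-log g_y`.
#' Scores exactly at 0 or 1 are a domain error (pool ingestion clips scores
#' so this cannot arise from a [test_pool()]).
#'
#' @param score Binary score vector or multiclass score matrix.
#' @param label 0/1 labels (binary) or 1-based class indices (multiclass).
#' @return Nonnegative, finite loss per record.
#' @examples
#' cross_entropy_loss(0.5, 1)   # log 2
#' @export
cross_entropy_loss <- function(score, label) {
  if (is.matrix(score)) {
    bad <- which(apply(score, 1L, function(z) any(z <= 0 | z >= 1)))
    if (length(bad))
      stop(sprintf("cross_entropy_loss: score at 0 or 1 for record(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    -log(score[cbind(seq_len(nrow(score)), as.integer(label))])
  } else {
    bad <- which(score <= 0 | score >= 1)
    if (length(bad))
      stop(sprintf("cross_entropy_loss: score at 0 or 1 for record(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    -(label * log(score) + (1 - label) * log(1 - score))
  }
}

#' Pointwise squared-error loss
#'
#' @param score Binary score vector (multiclass squared error is not plumbed).
#' @param label 0/1 labels.
#' @return `(score - label)^2` per record.
#' @export
squared_error_loss <- function(score, label) {
  (score - label)^2
}

#' Evaluate a loss spec pointwise
#'
#' @param spec A [loss_spec()].
#' @param score,label As in [cross_entropy_loss()].
#' @return Loss per record.
#' @export
pointwise_loss <- function(spec, score, label) {
  switch(spec$name,
         cross_entropy = cross_entropy_loss(score, label),
         squared_error = squared_error_loss(score, label))
}

# component functions d1/d2 for the built-in ratio metrics at cutoff c;
# indicators use strict inequalities (score > c, and score < c for NPV), so a
# score exactly at the cutoff counts as "not above".
.metric_table <- list(
  TPR = function(z1, z2, c) cbind((z1 > c) * z2, z2),
  FPR = function(z1, z2, c) cbind((z1 > c) * (1 - z2), 1 - z2),
  PPV = function(z1, z2, c) cbind((z1 > c) * z2, as.numeric(z1 > c)),
  NPV = function(z1, z2, c) cbind((z1 < c) * (1 - z2), as.numeric(z1 < c)),
  F1  = function(z1, z2, c) cbind((z1 > c) * z2, (z1 > c) + z2)
)

#' Ratio-metric specification
#'
#' Ratio-form predictive accuracy metrics are defined as
#' `D = E[d1{g(X), Y}] / E[d2{g(X), Y}]` for component functions `(d1, d2)` at
#' a risk cutoff `c`. Built-in components:
#'
#' | metric | d1              | d2              |
#' |--------|-----------------|-----------------|
#' | TPR    | `I(z1>c) z2`    | `z2`            |
#' | FPR    | `I(z1>c)(1-z2)` | `1-z2`          |
#' | PPV    | `I(z1>c) z2`    | `I(z1>c)`       |
#' | NPV    | `I(z1<c)(1-z2)` | `I(z1<c)`       |
#' | F1     | `I(z1>c) z2`    | `I(z1>c) + z2`  |
#'
#' The F1 row is computed verbatim from these components, whose ratio equals
#' TP / (predicted-positives + positives), i.e. half the conventional
#' F1 = 2TP / (predicted-positives + positives). [conventional_f1()] exposes
#' the doubled value.
#'
#' @param name One of `"TPR"`, `"FPR"`, `"PPV"`, `"NPV"`, `"F1"`, or
#'   `"custom"` with `d1` and `d2` supplied.
#' @param cutoff Risk cutoff `c` in (0,1).
#' @param d1,d2 For `name = "custom"`: functions of `(z1, z2)` returning
#'   nonnegative component values.
#' @return An object of class `"metric_spec"`.
#' @export
metric_spec <- function(name = c("TPR", "FPR", "PPV", "NPV", "F1", "custom"),
                        cutoff = 0.5, d1 = NULL, d2 = NULL) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown metric name: ", name[1L]))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  if (name == "custom") {
    if (!is.function(d1) || !is.function(d2))
      stop("custom metrics require d1 and d2 functions")
    fun <- function(z1, z2, c) cbind(d1(z1, z2), d2(z1, z2))
  } else {
    fun <- .metric_table[[name]]
  }
  structure(list(name = name, cutoff = cutoff, components = fun),
            class = "metric_spec")
}

#' Evaluate ratio-metric component functions
#'
#' @param spec A [metric_spec()].
#' @param score Binary scores `z1`.
#' @param label 0/1 labels `z2`.
#' @return Two-column matrix of `(d1, d2)` values per record.
#' @export
metric_components <- function(spec, score, label) {
  out <- spec$components(score, label, spec$cutoff)
  colnames(out) <- c("d1", "d2")
  out
}

#' Full-data benchmark of a performance metric
#'
#' Uses every label in the pool (simulation mode) to compute the empirical
#' target value: the mean loss for a [loss_spec()], or the ratio of the
#' unweighted component sums for a [metric_spec()]. Estimator simulations
#' compare against this value.
#'
#' @param pool A labeled [test_pool()].
#' @param target A [loss_spec()] or [metric_spec()].
#' @return The benchmark value.
#' @export
full_data_benchmark <- function(pool, target) {
  y <- all_labels(pool)
  if (inherits(target, "loss_spec")) {
    mean(pointwise_loss(target, pool$scores, y))
  } else if (inherits(target, "metric_spec")) {
    dd <- metric_components(target, pool$scores, y)
    if (sum(dd[, 2L]) <= 0)
      stop(sprintf("metric %s undefined: zero d2 sum", target$name))
    sum(dd[, 1L]) / sum(dd[, 2L])
  } else {
    stop("target must be a loss_spec or metric_spec")
  }
}

#' Conventional F1 from the component-form ratio
#'
#' The component table's F1 row yields TP / (predicted-positives + positives);
#' the conventional F1 score doubles it.
#'
#' @param ratio Value of the component-form F1 ratio.
#' @return `2 * ratio`.
#' @export
conventional_f1 <- function(ratio) 2 * ratio
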