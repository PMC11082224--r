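#' Construct a test pool for active model evaluation
#'
#' A test pool holds the evaluated model's prediction scores for `N` records,
#' together with (in simulation mode) the true outcome labels, which are kept
#' behind a label oracle: estimation code may only read the label of a record
#' after it has been selected for labeling (see [oracle_labels()]). Optional
#' covariates are carried along for pluggable auxiliary probability models.
#'
#' Scores are clipped into `[clip, 1 - clip]` at ingestion so that
#' cross-entropy losses are always finite; the number of clipped records is
#' recorded in the `n_clipped` field. Multiclass score vectors must lie on the
#' probability simplex (rows summing to 1 within `1e-9`) and are renormalized
#' after clipping.
#'
#' @param scores Numeric vector of binary prediction scores in (0,1), or a
#'   numeric matrix with one column per class for multiclass models.
#' @param labels Optional outcome labels: 0/1 for binary scores, or 1-based
#'   class indices matching the score columns for multiclass. Only needed in
#'   simulation mode (full-data benchmarks, label oracle).
#' @param covariates Optional numeric matrix of per-record features.
#' @param true_probs Optional true conditional outcome probabilities (same
#'   shape as `scores`); retained only for oracle checks in simulations.
#' @param clip Clipping margin applied to scores at ingestion.
#' @return An object of class `"test_pool"` with fields `n`, `scores`,
#'   `n_classes` (2 for binary), `covariates`, `true_probs`, `n_clipped`.
#' @examples
#' pool <- test_pool(c(0.2, 0.8), labels = c(0, 1))
#' pool$n
#' @export
test_pool <- function(scores, labels = NULL, covariates = NULL,
                      true_probs = NULL, clip = 1e-12) {
  if (is.matrix(scores)) {
    if (ncol(scores) < 2L)
      stop("multiclass score matrices need at least 2 columns")
    rs <- rowSums(scores)
    if (any(scores < 0) || any(abs(rs - 1) > 1e-9))
      stop("multiclass scores must be nonnegative and sum to 1 (tol 1e-9)")
    n_clipped <- sum(apply(scores, 1L, function(z) any(z < clip | z > 1 - clip)))
    scores <- pmin(pmax(scores, clip), 1 - clip)
    scores <- scores / rowSums(scores)
    n <- nrow(scores)
    n_classes <- ncol(scores)
  } else {
    scores <- as.numeric(scores)
    if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
      stop("binary scores must be finite and within [0, 1]")
    n_clipped <- sum(scores < clip | scores > 1 - clip)
    scores <- pmin(pmax(scores, clip), 1 - clip)
    n <- length(scores)
    n_classes <- 2L
  }
  if (n < 1L) stop("a test pool needs at least one record")
  if (n_clipped > 0L)
    message(sprintf("test_pool: clipped scores of %d record(s) into (0, 1)", n_clipped))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must match the number of records")
    if (is.matrix(scores)) {
      if (any(labels < 1L | labels > n_classes))
        stop("multiclass labels must be class indices in 1..C")
    } else if (any(labels != 0L & labels != 1L)) {
      stop("binary labels must be 0 or 1")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per record")
  }
  structure(
    list(n = n, scores = scores, n_classes = n_classes,
         covariates = covariates, true_probs = true_probs,
         labels = labels, n_clipped = n_clipped),
    class = "test_pool")
}

#' @export
print.test_pool <- function(x, ...) {
  kind <- if (is.matrix(x$scores)) sprintf("multiclass (C = %d)", x$n_classes) else "binary"
  cat(sprintf("Test pool: %d records, %s scores, labels %s\n",
              x$n, kind, if (is.null(x$labels)) "absent" else "held by oracle"))
  invisible(x)
}

#' Read labels through the label oracle
#'
#' Labels may only be revealed for records that the ledger marks as labeled;
#' requesting the label of an unselected record is an error. This enforces the
#' active-testing contract that the evaluator never sees outcomes it did not
#' pay to label.
#'
#' @param pool A [test_pool()].
#' @param ledger A [label_ledger()] tracking selections.
#' @param indices Record indices to reveal; defaults to all labeled records.
#' @return Integer labels for `indices`.
#' @export
oracle_labels <- function(pool, ledger, indices = which(ledger$delta == 1L)) {
  if (is.null(pool$labels))
    stop("pool carries no labels; the oracle cannot reveal outcomes")
  if (length(indices) == 0L) return(integer(0))
  if (any(indices < 1L | indices > pool$n))
    stop("oracle_labels: record index out of range")
  bad <- indices[ledger$delta[indices] != 1L]
  if (length(bad) > 0L)
    stop(sprintf("oracle_labels: record(s) %s are not labeled",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  pool$labels[indices]
}

#' Full labels for simulation benchmarks
#'
#' Bypasses the label oracle. Only meaningful in simulation mode, where the
#' pool was generated with known labels and a full-data benchmark is wanted.
#'
#' @param pool A [test_pool()].
#' @return Integer label vector of length `N`.
#' @export
all_labels <- function(pool) {
  if (is.null(pool$labels))
    stop("pool carries no labels (not a simulation pool)")
  pool$labels
}

#' Selection ledger for the active-testing loop
#'
#' Tracks, per record, the cumulative inclusion indicator, the step at which a
#' record was first selected, and the true and kernel-estimated selection
#' probabilities at that step. The cumulative indicator is monotone: once a
#' record is labeled it stays labeled, and its sampling probability at all
#' later steps is 1.
#'
#' @param n Number of records in the pool.
#' @return An object of class `"label_ledger"`.
#' @export
label_ledger <- function(n) {
  structure(
    list(step = 0L,
         delta = integer(n),
         selection_step = rep(NA_integer_, n),
         prob_true = rep(NA_real_, n),
         prob_est = rep(NA_real_, n),
         new_counts = integer(0)),
    class = "label_ledger")
}

#' Record one completed sampling step in the ledger
#'
#' @param ledger A [label_ledger()].
#' @param selected Global indices of the records newly selected at this step.
#' @param prob_true True selection probabilities of the selected records at
#'   this step.
#' @return The updated ledger (step counter advanced by one).
#' @export
ledger_update <- function(ledger, selected, prob_true) {
  if (length(selected) != length(prob_true))
    stop("selected and prob_true must align")
  if (any(ledger$delta[selected] == 1L))
    stop("cannot re-select an already labeled record")
  if (length(prob_true) && any(prob_true <= 0 | prob_true > 1))
    stop("selection probabilities must lie in (0, 1]")
  s <- ledger$step + 1L
  ledger$delta[selected] <- 1L
  ledger$selection_step[selected] <- s
  ledger$prob_true[selected] <- prob_true
  ledger$new_counts <- c(ledger$new_counts, length(selected))
  ledger$step <- s
  ledger
}

#' @export
print.label_ledger <- function(x, ...) {
  cat(sprintf("Label ledger: step %d, %d of %d records labeled\n",
              x$step, sum(x$delta), length(x$delta)))
  invisible(x)
}

#' Read a score table from CSV
#'
#' The column contract is: `id`; either `score` (binary) or `score_1` ..
#' `score_C` (multiclass); optional `label`; optional covariate columns
#' prefixed `x_`.
#'
#' @param path Path to a CSV file.
#' @param ... Passed to [test_pool()] (e.g. `clip`).
#' @return A [test_pool()]; record order follows the file.
#' @export
read_score_table <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  score_cols <- grep("^score(_[0-9]+)?$", nm, value = TRUE)
  if (length(score_cols) == 0L)
    stop("score table needs a 'score' column or 'score_1'..'score_C' columns")
  if (identical(score_cols, "score")) {
    scores <- df$score
  } else {
    idx <- as.integer(sub("^score_", "", score_cols))
    scores <- as.matrix(df[score_cols[order(idx)]])
    dimnames(scores) <- NULL
  }
  labels <- if ("label" %in% nm) df$label else NULL
  xc <- grep("^x_", nm, value = TRUE)
  covariates <- if (length(xc)) as.matrix(df[xc]) else NULL
  test_pool(scores, labels = labels, covariates = covariates, ...)
}

#' Write a pool to the score-table CSV contract
#'
#' @param pool A [test_pool()].
#' @param path Output CSV path.
#' @param include_labels Write the `label` column (simulation mode only).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(pool, path, include_labels = !is.null(pool$labels)) {
  df <- data.frame(id = seq_len(pool$n))
  if (is.matrix(pool$scores)) {
    sc <- as.data.frame(pool$scores)
    names(sc) <- paste0("score_", seq_len(ncol(pool$scores)))
    df <- cbind(df, sc)
  } else {
    df$score <- pool$scores
  }
  if (include_labels) df$label <- all_labels(pool)
  if (!is.null(pool$covariates)) {
    cv <- as.data.frame(pool$covariates)
    names(cv) <- paste0("x_", seq_len(ncol(pool$covariates)))
    df <- cbind(df, cv)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
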