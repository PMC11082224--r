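census_benchmarks <- function(pool, metrics) {
  ids <- vapply(metrics, metric_id, character(1L))
  vals <- numeric(length(metrics))
  curve <- NULL
  for (k in seq_along(metrics)) {
    mt <- metrics[[k]]
    if (is.character(mt)) {
      if (is.null(curve)) {
        led <- label_ledger(pool$n)
        led$delta[] <- 1L
        curve <- weighted_curve_metrics(led, pool$scores, all_labels(pool),
                                        rep(1, pool$n))
      }
      vals[k] <- unname(curve[mt])
    } else {
      vals[k] <- full_data_benchmark(pool, mt)
    }
  }
  stats::setNames(vals, ids)
}

#' Repeated active-testing experiment with benchmark comparison
#'
#' Runs `repetitions` independent repetitions of [active_test()] on a pool
#' with fully known labels, computes the full-data benchmark for every
#' metric, and summarizes estimation error per (step, estimator, metric) as
#' the root mean squared error over repetitions. Repetition-level randomness
#' is derived deterministically from `(seed, repetition)`, so the whole
#' experiment is reproducible. By default the pool is fixed across
#' repetitions (only the sampling is random); supply `pool_generator` to
#' regenerate the pool each repetition.
#'
#' @param pool A labeled [test_pool()] (ignored when `pool_generator` given).
#' @param repetitions Number of repetitions `R` (at least 2).
#' @param seed Base integer seed.
#' @param pool_generator Optional `function(rep_seed)` returning a labeled
#'   pool for each repetition.
#' @param ... Passed to [active_test()] (steps, n_s, prob_update, metrics, ...).
#' @return An object of class `"at_experiment"` with fields `estimates`
#'   (with a `repetition` column), `benchmark` (named by metric), `rmse`
#'   (data frame `step`, `estimator`, `metric`, `rmse`) and `config`.
#' @examples
#' pool <- generate_pool(synthetic_spec(n = 400, seed = 3))
#' ex <- at_experiment(pool, repetitions = 3, seed = 5, steps = 2, n_s = 40)
#' head(ex$rmse)
#' @export
at_experiment <- function(pool = NULL, repetitions = 100, seed = 1,
                          pool_generator = NULL, ...) {
  if (repetitions < 2L) stop("at_experiment needs at least 2 repetitions")
  if (is.null(pool) && is.null(pool_generator))
    stop("supply a pool or a pool_generator")
  dots <- list(...)
  metrics <- if (!is.null(dots$metrics)) dots$metrics
             else list(loss_spec("cross_entropy"))
  fixed_bench <- if (!is.null(pool) && is.null(pool_generator))
    census_benchmarks(pool, metrics)
  reps <- vector("list", repetitions)
  bench_sum <- NULL
  for (r in seq_len(repetitions)) {
    rep_seed <- step_seed(seed, r, 0L)
    pool_r <- if (is.null(pool_generator)) pool else pool_generator(rep_seed)
    bench_r <- if (is.null(pool_generator)) fixed_bench
               else census_benchmarks(pool_r, metrics)
    if (is.null(bench_sum)) bench_sum <- bench_r * 0
    bench_sum <- bench_sum + bench_r
    fit <- active_test(pool_r, ..., seed = seed, rep_id = r)
    est <- fit$estimates
    est$repetition <- r
    est$benchmark <- bench_r[est$metric]
    reps[[r]] <- est
  }
  estimates <- do.call(rbind, reps)
  benchmark <- bench_sum / repetitions
  rmse <- rmse_curve(estimates, benchmark = NULL)
  structure(list(estimates = estimates, benchmark = benchmark, rmse = rmse,
                 config = c(list(repetitions = repetitions, seed = seed), dots)),
            class = "at_experiment")
}

#' RMSE of estimates against the benchmark
#'
#' For each (step, estimator, metric) cell, the square root of the mean over
#' repetitions of the squared deviation from the benchmark.
#'
#' @param estimates Data frame with columns `repetition`, `step`,
#'   `estimator`, `metric`, `value`, and either a `benchmark` column or a
#'   `benchmark` argument.
#' @param benchmark Named numeric vector (by metric), or `NULL` to use the
#'   `benchmark` column.
#' @return Data frame `step`, `estimator`, `metric`, `rmse`.
#' @export
rmse_curve <- function(estimates, benchmark = NULL) {
  if (nrow(estimates) == 0L) stop("no estimates to summarize")
  dev <- if (!is.null(benchmark)) estimates$value - benchmark[estimates$metric]
         else if ("benchmark" %in% names(estimates))
           estimates$value - estimates$benchmark
         else stop("no benchmark supplied")
  agg <- stats::aggregate(list(mse = dev^2),
                          by = estimates[c("step", "estimator", "metric")],
                          FUN = mean)
  agg$rmse <- sqrt(agg$mse)
  agg$mse <- NULL
  agg[order(agg$metric, agg$estimator, agg$step), ]
}

#' Relative efficiency against a reference method/step
#'
#' `RE = MSE(method, step) / MSE(reference method, reference step)`, with MSE
#' the squared RMSE from [rmse_curve()]. The reference cell itself has
#' `RE = 1`; values below 1 mean the cell attains a smaller MSE than the
#' reference does at its own step (i.e. the reference needs more labels for
#' the same precision).
#'
#' @param rmse Data frame from [rmse_curve()].
#' @param estimator,metric,step Identify the reference cell.
#' @return `rmse` with an added `re` column.
#' @export
relative_efficiency <- function(rmse, estimator, metric, step) {
  ref <- rmse$rmse[rmse$estimator == estimator & rmse$metric == metric &
                     rmse$step == step]
  if (length(ref) != 1L) stop("reference cell not found")
  if (ref <= 0) stop("reference MSE is zero; relative efficiency undefined")
  rmse$re <- rmse$rmse^2 / ref^2
  rmse
}

#' Sweep (steps, subsample size) combinations at a fixed labeling budget
#'
#' Runs [at_experiment()] for each `(steps, n_s)` combination and reports the
#' final-step RMSE per estimator and metric. All combinations must spend the
#' same expected total label budget `steps * n_s`.
#'
#' @param pool A labeled [test_pool()].
#' @param combos List of length-2 vectors `c(steps, n_s)`.
#' @param repetitions,seed Passed to [at_experiment()].
#' @param ... Further arguments for [active_test()].
#' @return Data frame `steps`, `n_s`, `estimator`, `metric`, `rmse` (final
#'   step of each combination).
#' @export
subsample_size_sweep <- function(pool, combos, repetitions = 200, seed = 1, ...) {
  budgets <- vapply(combos, function(cm) cm[1L] * cm[2L], numeric(1L))
  if (length(unique(budgets)) != 1L)
    stop("all (steps, n_s) combinations must have the same total budget")
  out <- lapply(combos, function(cm) {
    ex <- at_experiment(pool, repetitions = repetitions, seed = seed,
                        steps = cm[1L], n_s = cm[2L], ...)
    fin <- ex$rmse[ex$rmse$step == max(ex$rmse$step), ]
    data.frame(steps = cm[1L], n_s = cm[2L], estimator = fin$estimator,
               metric = fin$metric, rmse = fin$rmse)
  })
  do.call(rbind, out)
}

#' @export
print.at_experiment <- function(x, ...) {
  cat(sprintf("Active-testing experiment: %d repetitions\n",
              x$config$repetitions))
  cat("Benchmarks:\n")
  print(round(x$benchmark, 4))
  cat("Final-step RMSE:\n")
  fin <- x$rmse[x$rmse$step == max(x$rmse$step), ]
  print(fin, row.names = FALSE)
  invisible(x)
}

#' @export
plot.at_experiment <- function(x, metric = names(x$benchmark)[1L], ...) {
  rm <- x$rmse[x$rmse$metric == metric, ]
  ests <- unique(rm$estimator)
  steps <- sort(unique(rm$step))
  mat <- sapply(ests, function(e) rm$rmse[rm$estimator == e][order(rm$step[rm$estimator == e])])
  graphics::matplot(steps, mat, type = "b", pch = 19, lty = 1,
                    xlab = "sampling step", ylab = paste("RMSE:", metric), ...)
  graphics::legend("topright", legend = ests, col = seq_along(ests),
                   pch = 19, bty = "n")
  invisible(x)
}

#' Tidy export of experiment estimates
#'
#' Writes the per-repetition estimate records as a tidy CSV with columns
#' `repetition`, `step`, `estimator`, `metric`, `value`.
#'
#' @param experiment An [at_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(experiment, path) {
  utils::write.csv(
    experiment$estimates[c("repetition", "step", "estimator", "metric", "value")],
    path, row.names = FALSE)
  invisible(path)
}
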