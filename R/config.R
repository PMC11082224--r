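#' Parse a flat key/value experiment configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric; comma-separated values become vectors.
#' Recognized keys (all optional unless noted):
#' `score_table` (CSV path, required for `run`), `n_records`, `n_features`,
#' `outcome`, `classes`, `miscalibration_a`, `miscalibration_b` (synthetic
#' pool, `simulate` mode), `steps`, `n_s`, `scheme`, `prob_update`,
#' `estimators`, `metrics`, `cutoff`, `kernel`, `bandwidth`, `prob_floor`,
#' `repetitions`, `seed`.
#'
#' @param path Path to the configuration file.
#' @return Named list of parsed values.
#' @export
parse_at_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

config_metrics <- function(cfg) {
  names <- if (is.null(cfg$metrics)) "cross_entropy" else cfg$metrics
  cutoff <- if (is.null(cfg$cutoff)) 0.5 else cfg$cutoff
  lapply(names, function(nm) {
    if (nm %in% c("cross_entropy", "squared_error")) loss_spec(nm)
    else if (nm %in% c("TPR", "FPR", "PPV", "NPV", "F1"))
      metric_spec(nm, cutoff = cutoff)
    else if (nm %in% c("auc", "auprc")) nm
    else stop("unknown metric in config: ", nm)
  })
}

config_args <- function(cfg) {
  args <- list()
  for (key in c("steps", "n_s", "scheme", "prob_update", "prob_floor"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$estimators)) args$estimators <- cfg$estimators
  args$metrics <- config_metrics(cfg)
  if (!is.null(cfg$kernel) || !is.null(cfg$bandwidth))
    args$kernel <- kernel_spec(
      kernel = if (is.null(cfg$kernel)) "gaussian" else cfg$kernel,
      bandwidth = cfg$bandwidth,
      rule = if (is.null(cfg$bandwidth)) "silverman" else "fixed")
  args
}

#' Command-line entry point
#'
#' Implements `activetest run --config FILE --out DIR` (evaluate a score
#' table under the configured active-testing experiment) and
#' `activetest simulate --config FILE --out DIR` (same on a generated
#' synthetic pool). Writes `estimates.csv`, `rmse.csv`, `re.csv` and
#' `run_log.txt` into the output directory. A ready-to-use launcher script
#' is installed at `system.file("cli", "activetest.R", package = "activetest")`.
#'
#' @param args Character vector of command-line arguments.
#' @return The [at_experiment()] result, invisibly.
#' @export
at_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: activetest (run|simulate) --config FILE --out DIR"
  if (length(args) < 1L || !args[1L] %in% c("run", "simulate")) stop(usage)
  mode <- args[1L]
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) != 1L || i == length(args)) stop(usage)
    args[i + 1L]
  }
  cfg <- parse_at_config(getopt("--config"))
  out_dir <- getopt("--out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  reps <- if (is.null(cfg$repetitions)) 100L else as.integer(cfg$repetitions)
  pool <- if (mode == "run") {
    if (is.null(cfg$score_table)) stop("run mode requires score_table=")
    read_score_table(cfg$score_table)
  } else {
    spec <- synthetic_spec(
      n = if (is.null(cfg$n_records)) 2000 else cfg$n_records,
      p = if (is.null(cfg$n_features)) 3 else cfg$n_features,
      outcome = if (is.null(cfg$outcome)) "binary" else cfg$outcome,
      classes = if (is.null(cfg$classes)) 3 else cfg$classes,
      miscalibration = c(
        if (is.null(cfg$miscalibration_a)) 0 else cfg$miscalibration_a,
        if (is.null(cfg$miscalibration_b)) 0.6 else cfg$miscalibration_b),
      seed = seed)
    generate_pool(spec)
  }
  ex <- do.call(at_experiment,
                c(list(pool = pool, repetitions = reps, seed = seed),
                  config_args(cfg)))
  write_estimates(ex, file.path(out_dir, "estimates.csv"))
  utils::write.csv(ex$rmse, file.path(out_dir, "rmse.csv"), row.names = FALSE)
  re <- relative_efficiency(ex$rmse,
                            estimator = ex$rmse$estimator[1L],
                            metric = ex$rmse$metric[1L],
                            step = max(ex$rmse$step))
  utils::write.csv(re, file.path(out_dir, "re.csv"), row.names = FALSE)
  writeLines(c(sprintf("activetest %s", as.character(utils::packageVersion("activetest"))),
               sprintf("mode: %s", mode),
               sprintf("seed: %d  repetitions: %d", seed, reps),
               sprintf("pool: %d records", pool$n),
               sprintf("benchmarks: %s",
                       paste(names(ex$benchmark), round(ex$benchmark, 6),
                             sep = "=", collapse = ", "))),
             file.path(out_dir, "run_log.txt"))
  invisible(ex)
}
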