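test_that("census runs return the benchmark for every estimator", {
  pool <- study_pool()
  small <- test_pool(pool$scores[1:60], labels = all_labels(pool)[1:60])
  fit <- active_test(small, steps = 1, n_s = 60,
                     estimators = c("LUR", "AILUR", "AIIPW", "IPW_oracle"),
                     seed = 1)
  bench <- full_data_benchmark(small, loss_spec("cross_entropy"))
  expect_equal(unname(coef(fit)), rep(bench, 4))
})

test_that("uniform single-step runs with equal losses return the common loss", {
  pool <- test_pool(rep(0.7, 40), labels = rep(1L, 40))
  fit <- suppressWarnings(  # constant scores degenerate the bandwidth rule
    active_test(pool, steps = 1, n_s = 10, scheme = "swr",
                prob_update = "Uniform",
                estimators = c("LUR", "AILUR", "AIIPW", "IPW_oracle"),
                seed = 2))
  expect_equal(unname(coef(fit)), rep(-log(0.7), 4), tolerance = 1e-10)
})

test_that("a fixed seed gives bit-identical traces and bookkeeping", {
  pool <- study_pool()
  f1 <- active_test(pool, steps = 2, n_s = 50, seed = 77)
  f2 <- active_test(pool, steps = 2, n_s = 50, seed = 77)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$ledger$delta, f2$ledger$delta)
  f3 <- active_test(pool, steps = 2, n_s = 50, seed = 78)
  expect_false(identical(f1$estimates$value, f3$estimates$value))
})

test_that("experiment records have the expected shape and bookkeeping", {
  pool <- generate_pool(synthetic_spec(n = 400, seed = 3))
  ex <- at_experiment(pool, repetitions = 2, seed = 5, steps = 2, n_s = 40,
                      estimators = c("LUR", "AIIPW"),
                      metrics = list(loss_spec("cross_entropy"),
                                     loss_spec("squared_error")))
  expect_equal(nrow(ex$estimates), 2 * 2 * 2 * 2)
  expect_named(ex$benchmark, c("cross_entropy", "squared_error"))
  expect_true(all(ex$rmse$rmse >= 0))
  expect_error(at_experiment(pool, repetitions = 1), "at least 2")
})

test_that("accumulating labels drives the RMSE down across steps", {
  ex <- cached("unif_lur", {
    at_experiment(study_pool(), repetitions = 200, seed = 19, steps = 3,
                  n_s = 100, prob_update = "Uniform", estimators = "LUR")
  })
  r <- ex$rmse[order(ex$rmse$step), ]
  expect_lt(r$rmse[3], r$rmse[1])
})

test_that("rmse_curve and relative efficiency match hand arithmetic", {
  est <- data.frame(repetition = 1:2, step = 1L, estimator = "LUR",
                    metric = "m", value = c(1, 3))
  expect_equal(rmse_curve(est, c(m = 2))$rmse, 1)
  expect_equal(rmse_curve(transform(est, value = 2), c(m = 2))$rmse, 0)
  shifted <- rmse_curve(transform(est, value = value + 5), c(m = 7))
  expect_equal(shifted$rmse, 1)

  rm <- data.frame(step = c(1L, 1L), estimator = c("A", "B"),
                   metric = "m", rmse = c(1, sqrt(0.5)))
  re <- relative_efficiency(rm, "A", "m", 1L)
  expect_equal(re$re, c(1, 0.5))  # half the reference MSE -> RE = 0.5
  re_k <- relative_efficiency(transform(rm, rmse = rmse * 3), "A", "m", 1L)
  expect_equal(re_k$re, re$re)    # invariant to rescaling all losses
  expect_error(relative_efficiency(rm, "C", "m", 1L), "not found")
  expect_error(relative_efficiency(transform(rm, rmse = c(0, 1)), "A", "m", 1L),
               "zero")
})

test_that("the budget sweep enforces equal budgets and reduces to one run", {
  pool <- generate_pool(synthetic_spec(n = 400, seed = 3))
  expect_error(subsample_size_sweep(pool, list(c(2, 100), c(3, 100))),
               "same total budget")
  sw <- subsample_size_sweep(pool, list(c(2, 40)), repetitions = 3, seed = 9,
                             estimators = "LUR")
  ex <- at_experiment(pool, repetitions = 3, seed = 9, steps = 2, n_s = 40,
                      estimators = "LUR")
  expect_equal(sw$rmse, ex$rmse$rmse[ex$rmse$step == 2])
})

test_that("configuration invariants are enforced", {
  pool <- generate_pool(synthetic_spec(n = 300, p = 2, seed = 4))
  expect_error(active_test(pool, steps = 4, n_s = 100), "exceeds the pool")
  expect_error(active_test(pool, steps = 1, n_s = 50, prob_update = "RF",
                           estimators = "AIIPW"),
               "function of the evaluated model")
  expect_error(active_test(test_pool(c(0.4, 0.6)), steps = 1, n_s = 1,
                           prob_update = "RF", estimators = "LUR"),
               "covariates")
})

test_that("ratio and curve metrics flow through the loop", {
  pool <- study_pool()
  fit <- active_test(pool, steps = 2, n_s = 100, estimators = "AIIPW",
                     metrics = list(metric_spec("TPR", 0.5), "auc", "auprc"),
                     seed = 23)
  vals <- coef(fit)
  expect_length(vals, 3)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(active_test(generate_pool(synthetic_spec(n = 200,
                             outcome = "multiclass", seed = 2)),
                           steps = 1, n_s = 50,
                           metrics = list(metric_spec("TPR"))),
               "binary pools")
})

test_that("swr scheme labels exactly n_s records per step", {
  pool <- study_pool()
  fit <- active_test(pool, steps = 2, n_s = 30, scheme = "swr", seed = 41,
                     estimators = "LUR")
  expect_identical(fit$ledger$new_counts, c(30L, 30L))
})
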