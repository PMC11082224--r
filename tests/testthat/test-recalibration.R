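test_that("linear-link recalibration solves the weighted normal equation", {
  fit <- solve_recalibration(c(0.4, 0.7), c(0.5, 1.0), c(1, 1), link = "linear")
  expect_equal(fit$theta, 0.72)
  expect_true(fit$converged)
})

test_that("logistic recalibration recovers the truth and scales out weights", {
  set.seed(15)
  g <- runif(2000, 0.05, 0.95)
  y <- rbinom(2000, 1, plogis(3 * g))
  fit <- solve_recalibration(y, g)
  expect_lt(abs(fit$theta - 3), 0.3)
  expect_lt(abs(fit$residual), 1e-8)
  fit2 <- solve_recalibration(y, g, weights = rep(5, 2000))
  expect_equal(fit2$theta, fit$theta, tolerance = 1e-8)
})

test_that("recovery bias shrinks with the labeled sample size", {
  mad_n <- vapply(c(200, 1000, 5000), function(n) {
    set.seed(n + 1)
    err <- replicate(60, {
      g <- runif(n, 0.05, 0.95)
      y <- rbinom(n, 1, plogis(2 * g))
      solve_recalibration(y, g)$theta - 2
    })
    mean(abs(err))
  }, numeric(1))
  expect_true(all(diff(mad_n) < 0))
})

test_that("degenerate labeled sets fall back to the capped boundary", {
  fit <- solve_recalibration(rep(1L, 10), runif(10, 0.2, 0.8))
  expect_true(fit$fallback_used)
  expect_equal(fit$theta, 20)
  fit0 <- solve_recalibration(rep(0L, 10), runif(10, 0.2, 0.8))
  expect_equal(fit0$theta, -20)
})

test_that("recalibrated probabilities respect the link's monotonicity", {
  fit <- structure(list(theta = 0, link = "logistic", on_logit_scale = FALSE),
                   class = "recalibration_fit")
  expect_equal(recalibrated_probs(fit, c(0.2, 0.9)), c(0.5, 0.5))
  fit$theta <- 2
  p <- recalibrated_probs(fit, c(0.3, 0.6, 0.9))
  expect_true(all(diff(p) > 0))
  fit$theta <- 20
  expect_true(all(recalibrated_probs(fit, c(0.5, 0.9)) > 0.99))
})

test_that("logit-scale recalibration undoes a logit-scale miscalibration", {
  pool <- generate_pool(synthetic_spec(n = 4000, miscalibration = c(0, 0.4),
                                      seed = 5))
  set.seed(6)
  lab <- sample(pool$n, 2000)
  fit <- solve_recalibration(all_labels(pool)[lab], pool$scores[lab],
                             on_logit_scale = TRUE)
  rec <- recalibrated_probs(fit, pool$scores)
  expect_lt(abs(fit$theta - 1 / 0.4), 0.3)
  expect_lt(mean(abs(rec - pool$true_probs)),
            mean(abs(pool$scores - pool$true_probs)))
})

test_that("multiclass recalibration reduces to the binary path for C = 2", {
  set.seed(16)
  g1 <- runif(300, 0.1, 0.9)
  sc <- cbind(g1, 1 - g1)
  y <- ifelse(rbinom(300, 1, g1) == 1L, 1L, 2L)
  out <- multiclass_recalibrated_probs(y, sc)
  bin <- solve_recalibration(as.integer(y == 1L), g1)
  expect_equal(attr(out, "theta")[1], bin$theta)
  expect_equal(out[, 1], recalibrated_probs(bin, g1), ignore_attr = TRUE)
  expect_equal(rowSums(out), rep(1, 300))
})

test_that("multiclass recalibration keeps the simplex and flags absent classes", {
  set.seed(17)
  sc <- matrix(runif(900, 0.1, 0.9), 300, 3)
  sc <- sc / rowSums(sc)
  y <- sample(1:2, 300, replace = TRUE)  # class 3 never observed
  expect_warning(out <- multiclass_recalibrated_probs(y, sc), "class 3 absent")
  expect_equal(attr(out, "theta")[3], 1)
  expect_equal(max(abs(rowSums(out) - 1)), 0, tolerance = 1e-9)
  expect_error(multiclass_recalibrated_probs(rep(1L, 10), sc[1:10, ]),
               "at least 2")
})
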