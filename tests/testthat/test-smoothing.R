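test_that("silverman bandwidth follows the rule and its symmetries", {
  x <- rep(c(0, 1), each = 50)
  expect_equal(silverman_bandwidth(x),
               0.9 * min(sd(x), IQR(x) / 1.34) * 100^(-1 / 5))
  set.seed(5)
  z <- runif(40)
  expect_equal(silverman_bandwidth(3 * z), 3 * silverman_bandwidth(z))
  expect_warning(b <- silverman_bandwidth(rep(0.4, 10)), "degenerate")
  expect_equal(b, 0.05)
  expect_error(silverman_bandwidth(1), "at least 2")
})

test_that("NW regression handles degenerate, flat and symmetric cases", {
  expect_equal(nw_regress(0.7, 0.3, c(0, 0.5, 1)), rep(0.7, 3))
  set.seed(6)
  r <- runif(50); x <- runif(50)
  flat <- nw_regress(r, x, c(0.2, 0.9), kernel_spec(bandwidth = 1e6, rule = "fixed"))
  expect_equal(flat, rep(mean(r), 2), tolerance = 1e-6)
  expect_equal(nw_regress(c(0, 1), c(-1, 1), 0), 0.5)
  expect_error(nw_regress(numeric(0), numeric(0), 1), "empty support")
  expect_warning(
    out <- nw_regress(c(0, 1), c(0, 10), 5,
                      kernel_spec("epanechnikov", bandwidth = 0.5, rule = "fixed")),
    "zero kernel mass")
  expect_equal(out, 0.5)
  # 0/1 responses stay inside [0, 1]
  est <- nw_regress(rbinom(50, 1, 0.3), x, x)
  expect_true(all(est >= 0 & est <= 1))
})

test_that("step selection probability collapses to the proportion for flat structure", {
  set.seed(7)
  led <- label_ledger(100)
  led <- ledger_update(led, sample(100, 30), rep(0.3, 30))
  # constant conditioning score: kernel estimate is the selected proportion
  est <- suppressWarnings(  # constant support degenerates the bandwidth rule
    estimate_step_selection_prob(led, rep(0.5, 100)))
  expect_equal(unname(est[!is.na(est)]), rep(0.3, 100))
  # flat-kernel limit gives the overall new-selection fraction
  est2 <- estimate_step_selection_prob(led, runif(100),
                                       kernel_spec(bandwidth = 1e6, rule = "fixed"))
  expect_equal(unname(est2[!is.na(est2)]), rep(0.3, 100), tolerance = 1e-4)
  expect_error(estimate_step_selection_prob(label_ledger(5), rep(0.5, 5)),
               "no completed")
})

test_that("step selection probability is consistent for a smooth truth", {
  set.seed(8)
  n <- 5000
  g <- runif(n, 0.05, 0.95)
  led <- label_ledger(n)
  sel <- which(rbinom(n, 1, g) == 1)  # true P(select | g) = g
  led <- ledger_update(led, sel, g[sel])
  est <- estimate_step_selection_prob(led, g)
  expect_lt(mean(abs(est - g)), 0.05)
})

test_that("cumulative inclusion estimate matches closed forms", {
  set.seed(9)
  led <- label_ledger(200)
  led <- ledger_update(led, sample(200, 50), rep(0.25, 50))
  est <- suppressWarnings(  # constant support degenerates the bandwidth rule
    estimate_cumulative_inclusion(led, rep(0.4, 200)))
  expect_equal(est, rep(0.25, 200))
  est2 <- estimate_cumulative_inclusion(led, runif(200),
                                        kernel_spec(bandwidth = 1e6, rule = "fixed"))
  expect_equal(est2, rep(0.25, 200), tolerance = 1e-4)
  expect_error(estimate_cumulative_inclusion(label_ledger(5), rep(0.5, 5)),
               "no labeled")
})

test_that("estimation error decreases with the pool size", {
  maes <- vapply(c(500, 2000, 8000), function(n) {
    set.seed(n)
    g <- runif(n, 0.05, 0.95)
    led <- label_ledger(n)
    sel <- which(rbinom(n, 1, g / 2) == 1)
    led <- ledger_update(led, sel, (g / 2)[sel])
    mean(abs(estimate_step_selection_prob(led, g) - g / 2))
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})

test_that("the exact inclusion recursion matches its closed forms", {
  q <- rep(0.2, 10)
  steps <- list(q, q, q)
  expect_equal(true_cumulative_inclusion(steps), rep(1 - 0.8^3, 10))
  expect_equal(true_cumulative_inclusion(steps[1]), q)
  absorbing <- list(rep(1, 4), rep(0.3, 4), rep(0.7, 4))
  expect_equal(true_cumulative_inclusion(absorbing), rep(1, 4))
  expect_error(true_cumulative_inclusion(list()), "no step")
  expect_error(true_cumulative_inclusion(list(q, NULL)), "missing step")
})
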