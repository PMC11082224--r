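test_that("per-step weights follow the closed form and sum to s", {
  expect_equal(lur_weight(10, 1, 1), 1)
  expect_equal(lur_weight(10, 2, 1), 8 / 9)
  expect_equal(lur_weight(10000, 10, 5), 10000 * 9990 / (9995 * 9996))
  expect_gt(lur_weight(10000, 10, 5), 0.999)  # w_j -> 1 for N >> s
  for (s in c(1, 3, 7)) expect_equal(sum(lur_weight(50, s, 1:s)), s)
  expect_error(lur_weight(10, 2, 3), "1 <= j <= s")
  expect_error(lur_weight(10, 10, 1), "s < N")
})

test_that("LUR and AIIPW reproduce the 4-record worked example", {
  led <- manual_ledger(4, c(1L, 2L), c(0.5, 0.25))
  losses <- c(0.2, 0.4, NA, NA)
  expect_equal(lur_estimate(led, losses, "true"), 0.5)
  expect_equal(lur_estimate(led, losses, "estimated"), 0.5)
  expect_equal(aiipw_estimate(led, losses, c(0.5, 0.25, 1, 1)), 0.5)
  expect_equal(ipw_oracle_estimate(led, losses, c(0.5, 0.25, 1, 1)), 0.5)
  led$prob_est[2] <- NA
  expect_error(lur_estimate(led, losses, "estimated"), "missing stored")
  expect_error(aiipw_estimate(led, losses, c(0.5, -1, 1, 1)), "positive")
})

test_that("constant-loss and census identities hold exactly", {
  # s = 1, uniform pi = n/N with realized n* = n: the common loss comes back
  led <- manual_ledger(10, 1:5, rep(0.5, 5))
  expect_equal(lur_estimate(led, rep(0.3, 10), "true"), 0.3)
  # census: every record labeled with probability 1 at step 1
  losses <- runif(8)
  census <- manual_ledger(8, 1:8, rep(1, 8))
  expect_equal(lur_estimate(census, losses, "true"), mean(losses))
  expect_equal(lur_estimate(census, losses, "estimated"), mean(losses))
  expect_equal(aiipw_estimate(census, losses, rep(1, 8)), mean(losses))
  # flat weights cancel: AIIPW equals the labeled-sample mean loss
  part <- manual_ledger(10, 1:4, rep(0.4, 4))
  losses10 <- runif(10)
  expect_equal(aiipw_estimate(part, losses10, rep(0.4, 10)),
               mean(losses10[1:4]))
})

test_that("multi-step bookkeeping applies pi = 1 to earlier selections", {
  led <- label_ledger(6)
  led <- ledger_update(led, 1L, 0.5)
  led <- ledger_update(led, 2L, 0.25)
  losses <- c(0.3, 0.8, NA, NA, NA, NA)
  w <- lur_weight(6, 2, 1:2)
  by_hand <- (w[1] * 0.3 / 0.5 + w[2] * (0.3 + 0.8 / 0.25)) / (2 * 6)
  expect_equal(lur_estimate(led, losses, "true"), by_hand)
})

test_that("AIIPW needs only current-step quantities (memory contract)", {
  led <- manual_ledger(10, c(2L, 5L), c(0.3, 0.6))
  led$prob_true[] <- NA  # discard the probability history
  losses <- replace(rep(NA_real_, 10), c(2, 5), c(0.1, 0.2))
  expect_equal(aiipw_estimate(led, losses, rep(0.2, 10)),
               (0.1 + 0.2) / 0.2 / 10)
})

test_that("weighted ratio metrics match hand counts and invariances", {
  pool <- test_pool(c(0.9, 0.8, 0.2, 0.1), labels = c(1L, 0L, 1L, 0L))
  census <- manual_ledger(4, 1:4, rep(1, 4))
  y <- all_labels(pool)
  for (m in c("TPR", "FPR", "PPV", "F1")) {
    spec <- metric_spec(m, 0.5)
    expect_equal(aiipw_ratio_metric(census, spec, pool$scores, y, rep(1, 4)),
                 full_data_benchmark(pool, spec))
  }
  led2 <- manual_ledger(4, c(1L, 3L), c(0.5, 0.5))
  expect_equal(aiipw_ratio_metric(led2, metric_spec("TPR", 0.5),
                                  c(0.9, 0.5, 0.2, 0.5), c(1L, 0L, 1L, 0L),
                                  rep(0.5, 4)), 0.5)
  v1 <- aiipw_ratio_metric(led2, metric_spec("TPR", 0.5), pool$scores, y,
                           rep(0.5, 4))
  v2 <- aiipw_ratio_metric(led2, metric_spec("TPR", 0.5), pool$scores, y,
                           rep(0.5, 4) * 7)
  expect_equal(v1, v2)
  expect_error(aiipw_ratio_metric(led2, metric_spec("PPV", 0.99), pool$scores,
                                  y, rep(0.5, 4)), "zero weighted d2")
})

test_that("weighted AUC matches the pairwise-concordance oracle at census", {
  set.seed(13)
  n <- 150
  scores <- round(runif(n), 2)  # duplicates exercise tie handling
  labels <- rbinom(n, 1, plogis(4 * (scores - 0.5)))
  census <- manual_ledger(n, seq_len(n), rep(1, n))
  cm <- weighted_curve_metrics(census, scores, labels, rep(1, n))
  expect_equal(unname(cm["auc"]), pairwise_auc(scores, labels),
               tolerance = 1e-9)
  expect_true(cm["auprc"] > 0 && cm["auprc"] <= 1)

  sep <- c(rep(0.9, 5), rep(0.1, 5))
  ysep <- c(rep(1L, 5), rep(0L, 5))
  led <- manual_ledger(10, 1:10, rep(1, 10))
  cmsep <- weighted_curve_metrics(led, sep, ysep, rep(1, 10))
  expect_equal(unname(cmsep["auc"]), 1)
  expect_equal(unname(cmsep["auprc"]), 1)

  set.seed(14)
  ynull <- rbinom(400, 1, 0.5)
  lednull <- manual_ledger(400, 1:400, rep(1, 400))
  cmnull <- weighted_curve_metrics(lednull, runif(400), ynull, rep(1, 400))
  expect_lt(abs(cmnull["auc"] - 0.5), 0.1)

  expect_error(weighted_curve_metrics(led, sep, rep(1L, 10), rep(1, 10)),
               "one class")
})
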