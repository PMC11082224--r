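# shared fixtures and cached heavy experiments (computed at most once per run)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the packaged study pool: N = 2000, binary, miscalibration (0, 0.6)
study_pool <- function() cached("pool", generate_pool(synthetic_spec(seed = 42)))

# entropy sampling under the original model, all four estimators, R = 500
ori_experiment <- function() cached("ori", {
  at_experiment(study_pool(), repetitions = 500, seed = 2024,
                steps = 3, n_s = 100,
                estimators = c("LUR", "AILUR", "AIIPW", "IPW_oracle"))
})

# a ledger with the given records labeled at step 1 with given probabilities
manual_ledger <- function(n, labeled, prob, prob_est = prob) {
  led <- label_ledger(n)
  led <- ledger_update(led, labeled, prob)
  led$prob_est[labeled] <- prob_est
  led
}

# brute-force pairwise concordance AUC (tie-aware), the census oracle
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
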