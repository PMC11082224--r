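# activetest

Label-efficient evaluation of pre-trained classifiers by **active testing**:
sequentially choose which test-pool records to label, spending the budget on
informative records, then undo the resulting selection bias with
inverse-probability weighting.

The package is for statisticians and ML practitioners who must certify a
fixed model `g(·)` — a disease-risk classifier, an image model — on a test
pool of `N` records when outcome labels cost money or clinician time. It
implements three estimators of a performance metric
`M = E[L{g(X), Y}]`:

* **LUR** — the levelled unbiased risk estimator: per-step Horvitz–Thompson
  sums with step weights `w_j = N(N−s)/((N−j)(N−j+1))` and the true Poisson
  sampling probabilities. Exactly unbiased, but noisy when small
  probabilities occur.
* **AILUR** — LUR with each true selection probability replaced by a
  Nadaraya–Watson kernel estimate `P̂{δ^s=1 | g^s(X)}` computed on the
  previously-unlabeled support.
* **AIIPW** — weights each labeled record by a kernel estimate of the
  cumulative inclusion probability `Ê{δ^s | g(X)}`, so only the current
  step's weights are ever needed (memory-efficient), with the exact
  recursion `E[δ^s|g] = E[δ^{s−1}|g] + P(δ^s=1|g)·Π_{j<s}(1−P(δ^j=1|g))`
  available as a testing oracle.

Sampling probabilities follow the expected cross-entropy
`−[p·log g + (1−p)·log(1−g)]` under a plug-in `p`: the model's own scores
("Ori"), a pluggable auxiliary model ("RF"), constant ("Uniform"), or a
model **recalibrated** on the accumulated labels ("Rec") by solving
`Σ δ^s g_i [Y_i − h(θ g_i)]/Ê_i = 0` for the scalar `θ`. Ratio-form
accuracy metrics (TPR, FPR, PPV, NPV, F1 at a cutoff `c`) and weighted
AUC/AUPRC are estimated with the same inclusion weights. A synthetic-data
module generates pools with known truth and a controllably miscalibrated
evaluated model, so every estimator is testable without external data.

## Worked example

Evaluate a deliberately underconfident model (logits shrunk by 0.6) on a
synthetic pool of 2000 records, labeling ~100 per step for 3 steps:

```r
library(activetest)

pool <- generate_pool(synthetic_spec(n = 2000, seed = 42))
full_data_benchmark(pool, loss_spec("cross_entropy"))
#> [1] 0.5833733

fit <- active_test(pool, steps = 3, n_s = 100,
                   estimators = c("LUR", "AILUR", "AIIPW"), seed = 7)
summary(fit)
#> Active testing: poisson sampling, plug-in 'Ori'
#> Labeled 316 records over 3 step(s); per-step new labels: 97, 103, 116
#>  step        metric       LUR     AILUR     AIIPW
#>     1 cross_entropy 0.5328871 0.5750977 0.5750977
#>     2 cross_entropy 0.5762819 0.5900766 0.5840122
#>     3 cross_entropy 0.6143891 0.5985711 0.5971489
```

With 316 of 2000 labels bought, all three estimators sit near the full-data
benchmark 0.5834; the kernel-weighted AILUR/AIIPW track it noticeably more
tightly than LUR on this draw — the pattern that holds in expectation:
across 500 repetitions of this experiment the final-step RMSE is about
0.035 for LUR versus 0.015–0.017 for AILUR/AIIPW, and recalibrated sampling
(`prob_update = "Rec"`) brings AIIPW to about 0.17× LUR's MSE.

`at_experiment()` runs the repetition harness (RMSE curves, benchmarks),
`relative_efficiency()` compares methods, and `subsample_size_sweep()`
checks stability across `(steps, n_s)` schedules at a fixed label budget.
Score tables move in and out through a documented CSV contract
(`read_score_table()` / `write_score_table()`), and a command-line entry
point (`at_main()`; launcher in `inst/cli/activetest.R`) drives both real
(`run`) and synthetic (`simulate`) experiments from a flat config file.

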