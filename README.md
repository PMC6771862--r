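# psicatree

Probabilistic subgroup identification trees for randomized trials with
**categorical treatments** (m ≥ 2 arms, real-valued outcome).

Most tree-based subgroup discovery methods handle two arms and report mean
differences. `psicatree` instead answers, for every covariate-defined
subgroup, *"with what probability is each treatment the best one?"* — and
when the data cannot tell, it says so by labelling the subgroup with several
plausible best treatments instead of manufacturing a winner.

## Method in brief

Given trial data $D = \{(X_i, Y_i, t_i)\}_{i=1}^n$ with treatments
$\tau_1,\dots,\tau_m$:

1. **Per-arm outcome models.** Each arm gets a conditional-inference
   regression forest (bootstrap resampling; a node splits only when a
   covariate passes a Bonferroni-adjusted association test). Joint
   counterfactual samples $Y^b = (Y^b_1(x),\dots,Y^b_m(x))$ are drawn either
   from per-arm bootstrap ensembles, or from
   $N(M_k(x), \sigma_k^2(x))$ with the forest mean and its bias-corrected
   **infinitesimal-jackknife** variance. The best-arm probability is
   $$\pi_k(x) = \frac{1}{B}\sum_{b=1}^B
     I\!\left(Y^b_k(x) > \max_{j \neq k} Y^b_j(x)\right).$$
2. **Tree on probabilities.** A binary tree is grown on $(X_i, P_i)$,
   choosing splits that maximize the information gain of the misassignment
   cost loss $L(\Delta) = |\Delta| \sum_k \pi_k(\Delta)(1-\hat\pi_k(\Delta))$
   (zero–one costs; a general cost matrix is supported). A chi-square
   pre-pruning gate only allows splits whose children's probability
   distributions differ significantly at risk level $\alpha$. Each leaf
   reports $\pi_k(\Delta)$, the *useless* treatments (sorted cumulative
   probability mass ≤ α), the complementary *potential* set, and the
   truncated probabilities $\hat\pi_k$ renormalized over the potential set.

The package also ships the six-model synthetic benchmark (M1–M6: dominant
arms, qualitative interactions, Laplace noise, prognostic-only covariates,
three crossing lines, four arms with exact ties and a categorical
predictor) with exact ground truth, and the four evaluation metrics
(accuracy, uncertainty, suspect rate, decision accuracy).

## Worked example

```r
library(psicatree)

sim <- simulate_trial(make_model("M5"), n = 300, seed = 7)  # 3 crossing lines
fit <- psica(sim$data, B = 500, n_trees = 100, seed = 7)
print(fit)
```

```
Subgroup tree: n = 300, 4 leaves, treatments: tau1, tau2, tau3
root  n=300  Tp={tau1,tau2,tau3}  pi=(0.30, 0.24, 0.46)
  x1 <= 0.1397  n=163  Tp={tau1,tau2}  pi=(0.54, 0.43, 0.02)
    x1 <= -0.4368  n=69  Tp={tau2}  pi=(0.02, 0.98, 0.00) *
    x1 > -0.4368  n=94  Tp={tau1,tau3}  pi=(0.93, 0.03, 0.04)
      x1 <= 0.08359  n=84  Tp={tau1}  pi=(0.95, 0.04, 0.01) *
      x1 > 0.08359  n=10  Tp={tau1,tau3}  pi=(0.73, 0.00, 0.27) *
  x1 > 0.1397  n=137  Tp={tau3}  pi=(0.02, 0.00, 0.98) *
```

Reading: participants with `x1` above ≈ 0.14 should receive `tau3` (its
probability of being best there is 0.98); below ≈ −0.44, `tau2` is best
with probability 0.98; in between `tau1` dominates, with a small boundary
leaf honestly reporting `{tau1,tau3}`. The true crossings of this
generative model are at x = −0.5 and x ≈ 0.18.

```r
pred <- predict_sets(fit, sim$trial$X)
accuracy_metric(pred$potential, sim$truth)      # 0.96
uncertainty_metric(pred$potential, sim$truth)   # 0.033
suspect_metric(fit, "x1")                       # 0   (no noise-variable splits)
decision_accuracy(pred$pi_hat, sim$truth)       # 0.951
```

Artifacts (probabilities CSV, tree JSON, Graphviz DOT, run manifest) can be
written with `cmd_fit()`; `inst/cli/psicatree.R` wraps the pipeline for
shell use:

```sh
Rscript inst/cli/psicatree.R simulate --model M5 --n 900 --seed 7 --out trial.csv
Rscript inst/cli/psicatree.R fit --input trial.csv --out-dir run1 --seed 7
dot -Tpng run1/tree.dot -o tree.png
```

## Package layout

- `R/core.R` — validation, useless/potential treatment-set algebra
- `R/forest.R` — conditional-inference forests, IJ variance, bootstrap ensembles
- `R/probabilities.R` — joint outcome sampling, best-arm probability tables
- `R/tree.R` — loss, gain, chi-square gate, tree growth/pruning/prediction
- `R/simulate.R` — benchmark generators M1–M6 with ground truth
- `R/evaluate.R` — metrics and the replication harness
- `R/io.R`, `R/psica.R` — serialization, pipeline commands, one-call wrapper
- `vignettes/psica-trees.Rmd` — model, assumptions, design choices
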