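---
title: "Probabilistic subgroup identification trees: model, settings and design choices"
author: "psicatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic subgroup identification trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psicatree)
```

## The problem

A randomized trial compares $m \ge 2$ treatments $\tau_1, \dots, \tau_m$ on
$n$ participants. Each participant $i$ carries covariates $X_i$, receives one
treatment $t_i$, and yields one real-valued outcome $Y_i$; the counterfactual
outcomes under the other arms are never observed. Subgroup identification
asks: are there covariate-defined groups of participants for which some
treatments are clearly better than others — including *qualitative
interactions*, where the treatment ranking reverses between groups?

`psicatree` answers this with a two-stage procedure:

1. **Probability estimation.** For every participant, estimate
   $\pi_k(X_i)$ — the probability that arm $k$ would give the best outcome
   for someone with covariates $X_i$ — by fitting one outcome model per arm
   and simulating $B$ joint counterfactual outcome vectors.
2. **Tree summarization.** Grow a binary decision tree on the pairs
   $(X_i, P_i)$, $P_i = (\pi_1(X_i), \dots, \pi_m(X_i))$, so that each leaf
   reports aggregated probabilities, a set of *useless* treatments whose
   joint probability of being best is below a risk level $\alpha$, the
   complementary set of *potential* treatments, and the renormalized
   ("truncated") probabilities a decision-maker would act on.

The output is deliberately conservative: when the data cannot separate the
arms, the leaf label contains several (possibly all) treatments, which reads
as "collect more data" rather than a spurious recommendation.

## Stage 1: per-arm outcome models and joint sampling

The trial is split into its arms $D_k = \{i : t_i = \tau_k\}$. Each arm gets
a **conditional-inference regression forest**: trees grown on bootstrap
resamples that split a node only when some covariate shows a significant
association with the outcome. Concretely, at each node `mtry` randomly
chosen covariates are tested (a correlation $t$-test for numeric covariates,
a one-way ANOVA $F$-test for categorical ones), the smallest p-value is
Bonferroni-adjusted for the number of candidates, and the node becomes a
leaf unless it falls below `alpha_split`. The split point itself minimizes
the residual sum of squares within the selected variable.

Two details matter for calibration and were chosen deliberately:

* **Tests on distinct observations.** Association tests inside a bootstrap
  resample are computed on the *distinct* underlying observations of the
  node. Duplicated bootstrap rows are pseudo-replicates; counting them would
  inflate the test statistics and let trees split on noise.
* **A conservative `alpha_split` (default 0.005).** The forest's per-node
  test level controls how much noise structure can leak into the
  probability stage: anything the forests hallucinate in $\hat f_k(x)$
  reappears as covariate structure in $P$ and can be mistaken for a
  subgroup downstream. Genuine treatment effects in trial-sized data
  produce p-values many orders of magnitude below any conventional level,
  so the conservative default costs essentially no power while keeping
  per-arm predictions flat when there is nothing to find.

Joint outcome samples $Y^b = (Y^b_1(x), \dots, Y^b_m(x))$, $b = 1 \dots B$,
are then generated by one of two methods:

* **Jackknife method** (default): the forest mean $M_k(x)$ plus its
  sampling variance $\sigma_k^2(x)$ from the bias-corrected infinitesimal
  jackknife, with $Y^b_k(x) \sim N(M_k(x), \sigma_k^2(x))$ drawn
  independently across arms. The IJ estimate is
  $\sum_i \mathrm{Cov}_i^2 - (n_k/B_{trees})\, s^2(x)$, where
  $\mathrm{Cov}_i$ is the Monte-Carlo covariance between tree predictions
  and the $i$-th bootstrap inclusion count and $s^2$ the per-tree
  prediction variance.
* **Bootstrap method**: $B$ full models per arm, each fit to an independent
  bootstrap resample; sample $b$ is the $b$-th model's prediction. More
  faithful when outcomes are far from Gaussian, at roughly $B$-fold the
  cost.

$\pi_k(x)$ is the fraction of samples in which arm $k$ attains the maximum
(an exact tie splits the sample's mass equally among the tied arms, so each
probability row sums to one by construction). Draws at *every* participant's
covariates — not only the arm's own — give the counterfactual table the tree
stage needs.

**Numerical choice: a baseline variance floor.** At the default 100 trees
the IJ estimate is itself Monte-Carlo noisy and can undershoot to zero at
individual query points, which would make those rows spuriously
deterministic. The sampling step therefore floors $\sigma_k^2(x)$ at the
arm's bagged-mean variance $\widehat{\mathrm{var}}(y_k)/n_k$ — a forest
prediction cannot plausibly be estimated more precisely than the arm's
global mean. `ij_variance()` itself reports the raw estimate (floored only
at `1e-12` so sampling stays well-defined).

## Stage 2: the subgroup tree

Given a node $\Delta$ with aggregated probabilities
$\pi_k(\Delta) = \frac{1}{|\Delta|}\sum_{i \in \Delta} \pi_k(X_i)$, the
useless set $T_u$ collects the largest prefix of the increasingly sorted
$\pi_k(\Delta)$ whose cumulative mass stays $\le \alpha$ (ties sorted by
treatment index, so results are deterministic); $T_p$ is the complement and
is never empty. Truncated probabilities $\hat\pi_k$ renormalize $\pi_k$ over
$T_p$.

The node loss is the expected misassignment cost if participants are
assigned by the node's truncated distribution while each participant's truly
best arm follows their own probability row:
$$L(\Delta) = \sum_{i \in \Delta} \sum_{k=1}^m
  \sum_{j \in T_p,\, j \ne k} c_{kj}\, \hat\pi_j(\Delta)\, \pi_k(X_i),$$
which under the default zero–one costs collapses to
$L(\Delta) = |\Delta| \sum_k \pi_k(\Delta)\,(1 - \hat\pi_k(\Delta))$.
Because the inner sum factorizes through the node aggregate, the split
search evaluates the general form from cumulative column sums in $O(m)$ per
candidate; the package keeps both code paths and tests their identity on
random nodes.

Candidate splits are midpoints of consecutive distinct values for numeric
variables and all $2^{c-1}-1$ binary level partitions for categorical ones
(above `max_exhaustive_categories = 10` levels, a heuristic ordering of the
levels by their mean first-arm probability reduces the search to $c - 1$
ordered cuts — an approximation, since the exact ordering reduction does not
extend to vector responses). The split maximizing the information gain
$g = L(\Delta) - L(\Delta_1) - L(\Delta_2)$ is taken; growth stops when the
best gain is not strictly positive, when the node is smaller than
`min_node` (default $\lceil n/5 \rceil$), or at `max_depth`.

**Pre-pruning (default).** Each candidate's gain is multiplied by a gate
$G \in \{0, 1\}$: each child's aggregated probabilities are converted to
pseudo-counts $n_{kj} = \pi_k(\Delta_j)\,|\Delta_j|\,\omega_j$ with
inflation factor $\omega_j = (1/\sqrt{12}) / \mathrm{sd}_j$, where
$\mathrm{sd}_j$ pools *all* $m |\Delta_j|$ per-row probabilities of the
child, and a Pearson chi-square test on the resulting $m \times 2$ table
must reject at level $\alpha$ for the split to be allowed. Low-spread
(confident) children get inflated counts and hence more power; the
standard deviation is capped below at 0.005 so near-degenerate children do
not overflow. Degenerate tables (all-zero rows are dropped; fewer than two
rows left, or an empty column) fail the gate closed. The gate is applied to
every candidate by default (`gate_all_candidates`); a faster mode gates
only the best-by-gain candidate.

Design notes on genuinely open points:

* The pooling of the gate's standard deviation is over all arms and rows of
  a child (one $\omega_j$ per child) — the inflation factor carries a
  single child index, so a single pooled spread is the literal reading.
* The suspect denominator (below) includes leaves: "all nodes" read
  literally.
* Method A ("grow") still refuses non-positive gains; post-pruning
  utilities (`prune_tree` by depth, gain, or leaf count) collapse nodes
  using their stored summaries, so pruning never recomputes anything.
* Ties between equally good splits go to the lowest variable index, then
  the lowest threshold — determinism over elegance.

## Forest resolution

The benchmark settings tie minimum node sizes to the data: $\lceil n/5
\rceil$ for the subgroup tree and one tenth of the data for the forests.
The package resolves the *forest* fraction against the **arm** a forest
actually sees ($\lceil n_k/10 \rceil$), not the full trial: with the full-
$n$ reading an $m$-arm trial would give forest leaves spanning $m/10$ of
each arm, and piecewise-constant predictions that coarse blur exactly the
effect boundaries the tree stage is supposed to find (on the three-line
example below, the $x = 0.25$ crossing is unrecoverable at full-$n$
granularity). An explicit `min_split` overrides this default.

## The synthetic benchmark

`make_model()` provides six generative models (M1–M6) emulating the main
structures a subgroup method meets: a globally dominant arm with a
near-coincidence region (M1), qualitative quadrant interactions under
Gaussian and heavy-tailed Laplace noise (M2/M3), many prognostic-only
variables plus a few predictive ones (M4, 2 arms, 200 covariates), three
crossing linear responses (M5, and its shifted variant `M5_fig1` whose arm
crossings sit at $x = 0.25$ and $x = 10/17 \approx 0.588$), and a four-arm
model with an exact two-arm tie and a categorical predictive variable (M6).
Covariates are $U[-1,1]$ (M6 adds a four-level categorical), treatments are
assigned uniformly at random, and irrelevant $U[-1,1]$ covariates are
appended: two for M1/M2/M3/M5, 160 for M4/M6. The Laplace "scale squared"
notation is read as the scale parameter $b = 0.04$, paralleling the normal
variance notation. Ground truth $T_p(x)$ contains every arm within
$10^{-9}$ of the row-wise maximum of the expected-outcome surface, so only
exact ties produce multi-treatment truth.

What the generators do *not* emulate: covariate correlation, non-uniform
assignment, heteroscedastic or skewed noise beyond M3, missing data, and
outcome-model misspecification beyond what forests absorb. Passing the
benchmark therefore demonstrates internal correctness and calibration of
the machinery, not robustness to every failure mode of real trials.

## Metrics

With $T_p(x)$ the true best set and $\hat T_p(x)$ the leaf's potential set:

* **accuracy** — fraction of rows with $T_p(X_i) \subseteq \hat T_p(X_i)$.
  The containment runs this way because a tree predicting the full
  treatment set everywhere must score 100% accurate *and* 100% uncertain;
  the opposite direction is available behind a flag for sensitivity checks.
* **uncertainty** — fraction of rows with $|\hat T_p(X_i)| > |T_p(X_i)|$.
* **suspect** — the share of observation mass sitting immediately above
  splits on irrelevant variables: $\sum_{v \in \text{irrelevant splits}}
  |\Delta(v)| / \sum_{v \in \text{all nodes}} |\Delta(v)|$, undefined (NA)
  for a root-only tree and excluded from averages. "Irrelevant" means any
  variable absent from the model's predictive set — including M4/M6's
  main-effect-only variables, which shift outcomes in all arms equally and
  therefore cannot define a best-treatment subgroup.
* **decision accuracy** — probability that a treatment drawn from the
  row's truncated distribution is truly best. The default "expected" mode
  returns the exact expectation $\frac{1}{n}\sum_i \sum_{k \in T_p(X_i)}
  \hat\pi_k(X_i)$; a "sampled" mode draws one multinomial decision per row.

`run_experiment()` replicates simulate → estimate → grow → evaluate over a
(model, $n$, method) grid with independently derived seeds, recording
failures rather than dropping them; methods `m1`/`m2`/`m3` are jackknife
with `mtry = p`, jackknife with `mtry = sqrt(p)`, and bootstrap with
`mtry = sqrt(p)`.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | risk level for $T_u$, the gate, and hence label sets |
| `B` | 500 | joint outcome samples (Monte-Carlo resolution of $\pi$) |
| `n_trees` | 100 | trees per arm forest |
| `mtry` | `"all"` | candidate variables per forest split (`"all"` gave the best benchmark behavior; `"sqrt"` trades power for speed) |
| `min_node` | $\lceil n/5 \rceil$ | minimum tree-node size to split |
| forest `min_split` | $\lceil n_k/10 \rceil$ | minimum forest-node size to split |
| `min_bucket` | 5 | minimum forest child size |
| `alpha_split` | 0.005 | forest per-node association-test level |
| `direction` | `"higher"` | whether larger outcomes are better |
| costs | zero–one | misassignment cost matrix $c_{kj}$ |

Seeds: a single master seed drives everything; per-arm, per-tree,
per-bootstrap-member and sampling seeds are derived by a fixed counter
scheme, so identical inputs reproduce byte-identical artifacts.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_trial(make_model("M5"), n = 900, seed = 7)
fit <- psica(sim$data, seed = 7)       # B = 500, 100 trees, alpha = 0.05
print(fit)
pred <- predict_sets(fit, sim$trial$X)
accuracy_metric(pred$potential, sim$truth)
uncertainty_metric(pred$potential, sim$truth)
suspect_metric(fit, "x1")
```

Typical output on this model is a tree whose first split falls near the
true crossing between the second arm's line and the first, with leaves
labelled `{tau2}` on the left, `{tau1}` in the middle, `{tau3}` on the
right, and accuracy well above 0.9 with suspect 0 (the tests in
`tests/testthat/test-acceptance.R` assert exactly these behaviors at the
benchmark's settings; the replication counts there — 20 per cell — and
sample sizes 300–1800 are the package's chosen study scale).

## Known limitations

* Real-valued outcomes and randomized assignment only; no propensity
  adjustment, no categorical or survival outcomes, no missing-data
  handling.
* Correlations between a participant's counterfactual outcomes are not
  modelled — the observed data carry no information about them; draws are
  independent across arms.
* The bootstrap method at its benchmark setting ($B = 500$ forests per
  arm) is computationally heavy; the jackknife method is the practical
  default.
* Leaf probabilities are re-used from the growth sample; no honest
  held-out re-estimation is performed.
* The categorical split search above 10 levels is a heuristic ordering,
  not an exact reduction.
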