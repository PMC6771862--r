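# One-call interface: validate, estimate probabilities, grow the tree.

#' Fit a probabilistic subgroup-identification tree
#'
#' Convenience wrapper running the full pipeline on a trial data frame:
#' [validate_trial()], [fit_probabilities()] (per-arm forests, then Monte
#' Carlo best-arm counting) and [grow_tree()].
#'
#' @param data data frame with outcome, treatment and covariate columns.
#' @param outcome,treatment column names.
#' @param treatments optional treatment label order.
#' @param categorical covariates to force categorical.
#' @param method probability method: `"jackknife"` (forest mean + IJ
#'   variance) or `"bootstrap"`.
#' @param mtry `"all"`, `"sqrt"` or an integer.
#' @param B number of joint outcome samples (default 500).
#' @param n_trees trees per arm forest (default 100).
#' @param alpha risk level (default 0.05).
#' @param direction `"higher"` (default) or `"lower"` outcomes are better.
#' @param tree_method `"preprune"` (chi-square gated, default) or `"grow"`.
#' @param min_node_tree,min_node_forest minimum node sizes; defaults
#'   `ceiling(n/5)` and `ceiling(n/10)`.
#' @param max_depth optional tree depth cap.
#' @param costs optional m x m misassignment cost matrix (default
#'   zero-one).
#' @param seed master seed.
#' @return a `psica_tree` with the probability table attached as attribute
#'   `"probabilities"`.
#' @examples
#' sim <- simulate_trial(make_model("M5"), n = 300, seed = 1)
#' fit <- psica(sim$data, B = 100, n_trees = 50, seed = 1)
#' print(fit)
#' @export
psica <- function(data, outcome = "y", treatment = "t", treatments = NULL,
                  categorical = NULL, method = c("jackknife", "bootstrap"),
                  mtry = "all", B = 500L, n_trees = 100L, alpha = 0.05,
                  direction = c("higher", "lower"),
                  tree_method = c("preprune", "grow"),
                  min_node_tree = NULL, min_node_forest = NULL,
                  max_depth = Inf, costs = NULL, seed = 1L) {
  trial <- validate_trial(data, outcome = outcome, treatment = treatment,
                          treatments = treatments, categorical = categorical)
  P <- fit_probabilities(
    trial,
    forest_settings(n_trees = n_trees, mtry = mtry,
                    min_split = min_node_forest, seed = seed),
    prob_settings(method = match.arg(method), B = B,
                  direction = match.arg(direction), seed = seed)
  )
  tree <- grow_tree(trial, P,
                    tree_settings(alpha = alpha, min_node = min_node_tree,
                                  max_depth = max_depth,
                                  method = match.arg(tree_method),
                                  costs = costs))
  attr(tree, "probabilities") <- P
  tree
}
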