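# Performance metrics for subgroup trees against simulated ground truth:
# accuracy, uncertainty, suspect and decision accuracy, plus the replication
# harness for the simulation benchmark.

#' Accuracy of predicted best-treatment sets
#'
#' Fraction of rows whose TRUE best set is contained in the PREDICTED
#' potential set, so a tree that always predicts the full treatment set is
#' 100% accurate (and maximally uncertain). Set `direction = "pred_in_true"`
#' for the opposite containment as a sensitivity check.
#'
#' @param predicted,truth lists of treatment-label vectors, aligned by row.
#' @param direction containment direction (default `"true_in_pred"`).
#' @return scalar in \[0, 1\].
#' @export
accuracy_metric <- function(predicted, truth,
                            direction = c("true_in_pred", "pred_in_true")) {
  direction <- match.arg(direction)
  if (length(predicted) != length(truth)) stop("length mismatch")
  hit <- mapply(function(p, tr) {
    if (direction == "true_in_pred") all(tr %in% p) else all(p %in% tr)
  }, predicted, truth)
  mean(hit)
}

#' Uncertainty of predicted best-treatment sets
#'
#' Fraction of rows where the predicted set is strictly larger than the true
#' best set.
#'
#' @inheritParams accuracy_metric
#' @return scalar in \[0, 1\].
#' @export
uncertainty_metric <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  mean(lengths(predicted) > lengths(truth))
}

#' Suspect rate of a fitted tree
#'
#' Share of the tree's observation mass sitting immediately above splits on
#' irrelevant variables: the summed sizes of internal nodes whose split
#' variable is not predictive, divided by the summed sizes of ALL nodes
#' (internal and leaves). A root-only tree has no splits and the rate is
#' undefined (`NA`); callers exclude such trees when averaging.
#'
#' @param tree a `psica_tree`.
#' @param predictive_vars character vector of the variables that truly
#'   interact with treatment.
#' @return scalar in \[0, 1\], or `NA_real_` for a root-only tree.
#' @export
suspect_metric <- function(tree, predictive_vars) {
  nodes <- tree_nodes(tree)
  if (length(nodes) == 1L) return(NA_real_)
  denom <- sum(vapply(nodes, function(nd) nd$summary$size, numeric(1)))
  num <- sum(vapply(nodes, function(nd) {
    if (!is.null(nd$split) && !(nd$split$variable %in% predictive_vars)) {
      nd$summary$size
    } else 0
  }, numeric(1)))
  num / denom
}

#' Decision accuracy of leaf-level truncated probabilities
#'
#' Probability that a treatment drawn from each row's truncated distribution
#' is truly best for that row. `mode = "expected"` returns the exact
#' expectation `mean_i sum_{k in truth_i} pi_hat_ik`; `mode = "sampled"`
#' draws one treatment per row from the multinomial and reports the hit
#' fraction.
#'
#' @param pi_hat `n x m` matrix of truncated probabilities with treatment
#'   labels as column names.
#' @param truth list of true best-treatment label vectors.
#' @param mode `"expected"` (deterministic, default) or `"sampled"`.
#' @param seed RNG seed for sampled mode.
#' @return scalar in \[0, 1\].
#' @export
decision_accuracy <- function(pi_hat, truth, mode = c("expected", "sampled"),
                              seed = 1L) {
  mode <- match.arg(mode)
  pi_hat <- as.matrix(pi_hat)
  if (nrow(pi_hat) != length(truth)) stop("length mismatch")
  if (any(abs(rowSums(pi_hat) - 1) > 1e-6)) stop("pi_hat rows must sum to 1")
  labels <- colnames(pi_hat)
  if (is.null(labels)) stop("pi_hat must carry treatment labels as colnames")
  if (mode == "expected") {
    hits <- vapply(seq_len(nrow(pi_hat)),
                   function(i) sum(pi_hat[i, labels %in% truth[[i]]]),
                   numeric(1))
    return(mean(hits))
  }
  set.seed(seed)
  drawn <- apply(pi_hat, 1L, function(p) sample(labels, 1L, prob = p))
  mean(mapply(function(d, tr) d %in% tr, drawn, truth))
}

#' Full experiment grid for the simulation benchmark
#'
#' Estimation methods follow the benchmark's naming: `m1` = jackknife
#' probabilities with `mtry = p`, `m2` = jackknife with `mtry = sqrt(p)`,
#' `m3` = bootstrap ensembles with `mtry = sqrt(p)`.
#'
#' @param models character vector of model names.
#' @param ns sample sizes.
#' @param methods subset of `c("m1", "m2", "m3")`.
#' @param reps replicates per cell.
#' @param alpha risk level.
#' @param B joint outcome samples.
#' @param n_trees trees per forest.
#' @param seed master seed; each replicate derives its own.
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(models = "M5", ns = 300L, methods = "m1",
                            reps = 1L, alpha = 0.05, B = 500L,
                            n_trees = 100L, seed = 1L) {
  stopifnot(all(methods %in% c("m1", "m2", "m3")), reps >= 1L)
  structure(list(models = models, ns = as.integer(ns), methods = methods,
                 reps = as.integer(reps), alpha = alpha, B = as.integer(B),
                 n_trees = as.integer(n_trees), seed = seed),
            class = "experiment_grid")
}

#' @noRd
method_settings <- function(method, B, n_trees, seed) {
  switch(method,
         m1 = list(forest = forest_settings(n_trees = n_trees, mtry = "all"),
                   prob = prob_settings("jackknife", B = B, seed = seed)),
         m2 = list(forest = forest_settings(n_trees = n_trees, mtry = "sqrt"),
                   prob = prob_settings("jackknife", B = B, seed = seed)),
         m3 = list(forest = forest_settings(n_trees = n_trees, mtry = "sqrt"),
                   prob = prob_settings("bootstrap", B = B, seed = seed)),
         stop("unknown method: ", method))
}

#' Run one simulate / fit / grow / evaluate replicate
#'
#' @param model_name benchmark model name.
#' @param n sample size.
#' @param method `"m1"`, `"m2"` or `"m3"`.
#' @param seed replicate seed.
#' @inheritParams experiment_grid
#' @param tree_method `"preprune"` or `"grow"`.
#' @return one-row data frame of metrics (a `MetricReport` row).
#' @export
run_replicate <- function(model_name, n, method = "m1", seed = 1L,
                          alpha = 0.05, B = 500L, n_trees = 100L,
                          tree_method = "preprune") {
  sim <- simulate_trial(make_model(model_name), n, seed = seed)
  ms <- method_settings(method, B, n_trees, seed)
  P <- fit_probabilities(sim$trial, ms$forest, ms$prob)
  tree <- grow_tree(sim$trial, P,
                    tree_settings(alpha = alpha, method = tree_method))
  pred <- predict_sets(tree, sim$trial$X)
  data.frame(
    model = model_name, n = n, method = method, seed = seed,
    accuracy = accuracy_metric(pred$potential, sim$truth),
    uncertainty = uncertainty_metric(pred$potential, sim$truth),
    suspect = suspect_metric(tree, sim$model$predictive_vars),
    decision_accuracy = decision_accuracy(pred$pi_hat, sim$truth),
    n_leaves = n_leaves(tree),
    stringsAsFactors = FALSE
  )
}

#' Run a full benchmark grid
#'
#' Every (model, n, method) cell is replicated `reps` times with derived
#' seeds; a failing replicate is recorded with `NA` metrics and the error
#' message, never silently dropped.
#'
#' @param grid an [experiment_grid()] object.
#' @param verbose print progress.
#' @return data frame, one row per replicate, with an `error` column.
#' @export
run_experiment <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  out <- list()
  cell <- 0L
  for (model_name in grid$models) {
    for (n in grid$ns) {
      for (method in grid$methods) {
        cell <- cell + 1L
        for (r in seq_len(grid$reps)) {
          rep_seed <- derive_seed(grid$seed, stream = 20L + cell, index = r)
          row <- tryCatch(
            cbind(run_replicate(model_name, n, method, seed = rep_seed,
                                alpha = grid$alpha, B = grid$B,
                                n_trees = grid$n_trees),
                  replicate_id = r, error = NA_character_,
                  stringsAsFactors = FALSE),
            error = function(e) data.frame(
              model = model_name, n = n, method = method, seed = rep_seed,
              accuracy = NA_real_, uncertainty = NA_real_,
              suspect = NA_real_, decision_accuracy = NA_real_,
              n_leaves = NA_integer_, replicate_id = r,
              error = conditionMessage(e), stringsAsFactors = FALSE)
          )
          out[[length(out) + 1L]] <- row
          if (verbose) {
            message(sprintf("%s n=%d %s rep %d/%d done",
                            model_name, n, method, r, grid$reps))
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate replicate metrics into means and standard errors
#'
#' Suspect is averaged over the replicates where it is defined (root-only
#' trees are excluded from that average).
#'
#' @param results data frame from [run_experiment()].
#' @return data frame with one row per (model, n, method) cell.
#' @export
summarize_experiment <- function(results) {
  keys <- unique(results[, c("model", "n", "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$model == keys$model[i] & results$n == keys$n[i] &
                     results$method == keys$method[i], ]
    stat <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_))
      c(mean(v), stats::sd(v) / sqrt(length(v)))
    }
    a <- stat(sub$accuracy); u <- stat(sub$uncertainty)
    s <- stat(sub$suspect); d <- stat(sub$decision_accuracy)
    data.frame(model = keys$model[i], n = keys$n[i], method = keys$method[i],
               reps = nrow(sub), failures = sum(!is.na(sub$error)),
               accuracy = a[1], accuracy_se = a[2],
               uncertainty = u[1], uncertainty_se = u[2],
               suspect = s[1], suspect_se = s[2],
               decision_accuracy = d[1], decision_accuracy_se = d[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
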