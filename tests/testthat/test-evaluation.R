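test_that("accuracy counts containment of the true set in the prediction", {
  truth <- list("tau1", "tau2", c("tau1", "tau2"))
  full <- rep(list(c("tau1", "tau2", "tau3")), 3)
  expect_equal(accuracy_metric(full, truth), 1)
  expect_equal(accuracy_metric(truth, truth), 1)
  expect_equal(accuracy_metric(list("tau2", "tau1", "tau3"), truth), 0)
  expect_equal(accuracy_metric(list("tau1", "tau2", "tau1"), truth), 2 / 3)
  # sensitivity direction flips the containment
  expect_equal(accuracy_metric(list("tau1"), list(c("tau1", "tau2")),
                               direction = "pred_in_true"), 1)
  expect_error(accuracy_metric(truth, truth[1:2]), "length mismatch")
})

test_that("uncertainty counts strictly larger predictions", {
  truth <- list("tau1", "tau2", "tau3")
  expect_equal(uncertainty_metric(truth, truth), 0)
  expect_equal(uncertainty_metric(rep(list(paste0("tau", 1:3)), 3), truth), 1)
  # smaller prediction than truth is not uncertainty
  expect_equal(uncertainty_metric(list("tau1"), list(c("tau1", "tau2"))), 0)
})

test_that("suspect rate weighs nodes sitting above irrelevant splits", {
  # root (n = 100) split on a noise variable into two leaves of 50
  tree <- manual_tree(
    manual_split_node(1L, 0L, 100L, c(0.5, 0.5), "noise_1", 0,
                      manual_leaf(2L, 1L, 50L, c(0.9, 0.1)),
                      manual_leaf(3L, 1L, 50L, c(0.1, 0.9))),
    c("tau1", "tau2"), 100L)
  expect_equal(suspect_metric(tree, "x1"), 0.5)
  expect_equal(suspect_metric(tree, c("x1", "noise_1")), 0)

  root_only <- manual_tree(manual_leaf(1L, 0L, 100L, c(0.5, 0.5)),
                           c("tau1", "tau2"), 100L)
  expect_true(is.na(suspect_metric(root_only, "x1")))
})

test_that("pruning an irrelevant split never increases the suspect rate", {
  # depth-1 split on signal, depth-2 split on noise below it
  inner <- manual_split_node(2L, 1L, 60L, c(0.8, 0.2), "noise_1", 0,
                             manual_leaf(4L, 2L, 30L, c(0.85, 0.15)),
                             manual_leaf(5L, 2L, 30L, c(0.75, 0.25)),
                             gain = 0.5)
  tree <- manual_tree(
    manual_split_node(1L, 0L, 100L, c(0.6, 0.4), "x1", 0,
                      inner, manual_leaf(3L, 1L, 40L, c(0.2, 0.8)), gain = 2),
    c("tau1", "tau2"), 100L)
  s_before <- suspect_metric(tree, "x1")
  pruned <- prune_tree(tree, "max_depth", 1)
  s_after <- suspect_metric(pruned, "x1")
  expect_equal(s_before, 60 / (100 + 60 + 40 + 30 + 30))
  expect_equal(s_after, 0)
  expect_lte(s_after, s_before)
})

test_that("decision accuracy matches the truncated-probability expectation", {
  pi_hat <- matrix(c(0.45, 0.55), 1, 2,
                   dimnames = list(NULL, c("tau1", "tau2")))
  expect_equal(decision_accuracy(pi_hat, list("tau2")), 0.55)

  sure <- matrix(c(1, 0), 4, 2, byrow = TRUE,
                 dimnames = list(NULL, c("tau1", "tau2")))
  truth4 <- rep(list("tau1"), 4)
  expect_equal(decision_accuracy(sure, truth4), 1)
  expect_equal(decision_accuracy(sure, truth4, mode = "sampled"), 1)
  expect_error(decision_accuracy(sure * 2, truth4), "sum to 1")
})

test_that("sampled decisions converge to the expectation", {
  set.seed(1)
  n <- 1e5
  pi_hat <- rprob_rows(n, 3)
  colnames(pi_hat) <- paste0("tau", 1:3)
  truth <- lapply(sample(1:3, n, replace = TRUE), function(k) paste0("tau", k))
  exp_val <- decision_accuracy(pi_hat, truth)
  samp_val <- decision_accuracy(pi_hat, truth, mode = "sampled", seed = 2)
  expect_equal(samp_val, exp_val, tolerance = 3 * 0.5 / sqrt(n))
})

test_that("perfect predictions pin all metrics", {
  truth <- list("tau1", "tau2")
  pi_hat <- diag(2)
  colnames(pi_hat) <- c("tau1", "tau2")
  expect_equal(accuracy_metric(truth, truth), 1)
  expect_equal(uncertainty_metric(truth, truth), 0)
  expect_equal(decision_accuracy(pi_hat, truth), 1)
})

test_that("the experiment harness returns one seeded row per replicate", {
  grid <- experiment_grid(models = "M5", ns = 150L, methods = "m1",
                          reps = 2L, B = 80L, n_trees = 20L, seed = 9L)
  res1 <- run_experiment(grid)
  res2 <- run_experiment(grid)
  expect_equal(nrow(res1), 2L)
  expect_identical(res1, res2)
  expect_true(all(is.na(res1$error)))
  expect_true(all(res1$accuracy >= 0 & res1$accuracy <= 1))
  expect_true(all(res1$decision_accuracy >= 0 & res1$decision_accuracy <= 1))
  expect_equal(length(unique(res1$seed)), 2L)

  agg <- summarize_experiment(res1)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$reps, 2L)
  expect_equal(agg$accuracy, mean(res1$accuracy))
})

test_that("uncertainty responds antitonically to the risk level in aggregate", {
  # same fitted probabilities, increasingly permissive alpha
  u <- vapply(c(1e-5, 0.05, 0.5), function(a) {
    mean(vapply(1:6, function(r) {
      sim <- simulate_trial("M5", 240, seed = 600 + r)
      P <- fit_probabilities(sim$trial,
                             forest_settings(n_trees = 40, seed = r),
                             prob_settings(B = 120, seed = 600 + r))
      tree <- grow_tree(sim$trial, P, tree_settings(alpha = a))
      uncertainty_metric(predict_sets(tree, sim$trial$X)$potential, sim$truth)
    }, numeric(1)))
  }, numeric(1))
  # allow standard-error-level violations of the trend
  expect_lt(u[3], u[1] + 0.1)
  expect_lt(u[2], u[1] + 0.1)
})
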