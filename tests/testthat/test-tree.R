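test_that("node probability aggregation is the column mean", {
  expect_equal(aggregate_probabilities(matrix(c(0.2, 0.8), 1)), c(0.2, 0.8))
  expect_equal(aggregate_probabilities(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(1)
  P <- rprob_rows(40, 3)
  manual <- sapply(1:3, function(k) {
    acc <- 0
    for (i in 1:40) acc <- acc + P[i, k]
    acc / 40
  })
  expect_equal(aggregate_probabilities(P), manual, tolerance = 1e-12)
  expect_error(aggregate_probabilities(P[0, , drop = FALSE]), "empty node")
})

test_that("node loss evaluates the misassignment cost", {
  # all mass already on one treatment: nothing can be misassigned
  expect_equal(node_loss(matrix(c(1, 0), 5, 2, byrow = TRUE)), 0)
  # maximally uncertain node of 10 rows under zero-one cost
  P <- matrix(0.5, 10, 2)
  expect_equal(node_loss(P, alpha = 0.05), 5)
  expect_error(node_loss(P, costs = matrix(0, 3, 3)), "cost matrix")
})

test_that("general-cost and zero-one loss forms agree identically", {
  set.seed(2)
  for (rep in 1:200) {
    m <- sample(2:4, 1)
    P <- rprob_rows(sample(1:50, 1), m)
    expect_equal(node_loss(P, costs = zero_one_cost(m)), node_loss(P),
                 tolerance = 1e-12)
    # and both agree with the independent per-row oracle
    expect_equal(node_loss(P), oracle_loss(P), tolerance = 1e-10)
  }
})

test_that("information gain is loss additivity and vanishes for uninformative splits", {
  P <- matrix(rep(c(0.3, 0.7), 20), 20, 2, byrow = TRUE)
  expect_equal(information_gain(P, P[1:8, ], P[9:20, ]), 0, tolerance = 1e-12)

  pure <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                matrix(c(0, 1), 5, 2, byrow = TRUE))
  g <- information_gain(pure, pure[1:5, ], pure[6:10, ])
  expect_equal(g, node_loss(pure), tolerance = 1e-12)
  expect_gt(g, 0)
})

test_that("Pearson statistic on the inflated count table is computed correctly", {
  res <- psicatree:::pearson_chisq(rbind(c(30, 0), c(0, 30)))
  expect_equal(res$statistic, 60)
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 1e-10)
  # degenerate tables fail closed
  expect_equal(psicatree:::pearson_chisq(rbind(c(0, 0), c(1, 2)))$p_value, 1)
})

test_that("chi-square gate blocks identical children and is symmetric", {
  set.seed(3)
  P1 <- rprob_rows(30, 3)
  same <- chi_square_gate(P1, P1)
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_false(same$gate)

  P2 <- rprob_rows(30, 3)
  a <- chi_square_gate(P1, P2)
  b <- chi_square_gate(P2, P1)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$omegas, rev(b$omegas))

  # clearly different, confident children pass
  conf1 <- matrix(rep(c(0.97, 0.02, 0.01), 40), 40, 3, byrow = TRUE)
  conf2 <- matrix(rep(c(0.01, 0.02, 0.97), 40), 40, 3, byrow = TRUE)
  expect_true(chi_square_gate(conf1, conf2)$gate)
})

test_that("inflation factors weight confident children and are capped", {
  P_spread <- rprob_rows(50, 2)
  P_tight <- matrix(rep(c(0.5, 0.5), 50), 50, 2, byrow = TRUE) +
    cbind(rnorm(50, 0, 0.001), 0)
  P_tight <- P_tight / rowSums(P_tight)
  g <- chi_square_gate(P_spread, P_tight)
  expect_gt(g$omegas[2], g$omegas[1])
  expect_lte(g$omegas[2], (1 / sqrt(12)) / 0.005 + 1e-9)
})

test_that("split search returns nothing when the node is homogeneous", {
  X <- data.frame(x1 = rep(1, 20), x2 = rep(2, 20))
  P <- matrix(rep(c(0.4, 0.6), 20), 20, 2, byrow = TRUE)
  expect_null(best_split_search(X, P, tree_settings(method = "grow")))
})

test_that("a perfectly separating binary covariate is found", {
  X <- data.frame(x1 = rep(c(0, 1), each = 10))
  P <- rbind(matrix(c(0.98, 0.02), 10, 2, byrow = TRUE),
             matrix(c(0.02, 0.98), 10, 2, byrow = TRUE))
  s <- best_split_search(X, P, tree_settings(method = "grow"))
  expect_equal(s$variable, "x1")
  expect_equal(s$threshold, 0.5)
  expect_gt(s$gain, 0)
})

test_that("split search matches the exhaustive oracle on random instances", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    X <- data.frame(x1 = runif(n), x2 = runif(n),
                    x3 = factor(sample(letters[1:3], n, replace = TRUE)))
    P <- rprob_rows(n, 3)
    got <- best_split_search(X, P, tree_settings(method = "grow"))
    want <- oracle_best_split(X, P)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, want$variable)
      expect_equal(got$gain, want$g, tolerance = 1e-9)
      if (want$kind == "numeric") {
        expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
      } else {
        expect_setequal(got$left_categories, want$left_categories)
      }
    }
  }
})

test_that("gated split search agrees with the gated oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 60
    X <- data.frame(x1 = runif(n), x2 = runif(n))
    P <- rprob_rows(n, 3)
    got <- best_split_search(X, P, tree_settings(method = "preprune"))
    want <- oracle_best_split(X, P, gate = TRUE)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, want$variable)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    }
  }
})

test_that("trees on structureless probabilities stay at the root", {
  set.seed(6)
  X <- data.frame(x1 = runif(50), x2 = runif(50))
  P <- matrix(rep(c(0.2, 0.3, 0.5), 50), 50, 3, byrow = TRUE)
  tree <- grow_tree(X, P, tree_settings(min_node = 10))
  expect_equal(n_leaves(tree), 1L)

  # min_node larger than n forces a root-only tree on any data
  P2 <- rprob_rows(50, 3)
  tree2 <- grow_tree(X, P2, tree_settings(min_node = 51))
  expect_equal(n_leaves(tree2), 1L)
  expect_equal(tree2$root$summary$size, 50)
})

test_that("grown trees satisfy the structural invariants", {
  set.seed(7)
  n <- 200
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  P <- matrix(0, n, 2)
  P[, 1] <- plogis(5 * X$x1) * 0.96 + 0.02
  P[, 2] <- 1 - P[, 1]
  tree <- grow_tree(X, P, tree_settings(min_node = 20, method = "grow"))
  expect_gt(n_leaves(tree), 1L)
  for (nd in tree_nodes(tree)) {
    expect_equal(sum(nd$summary$pi), 1, tolerance = 1e-9)
    expect_equal(sum(nd$summary$pi_hat), 1, tolerance = 1e-9)
    expect_setequal(c(nd$summary$useless, nd$summary$potential),
                    tree$treatments)
    if (!is.null(nd$children)) {
      expect_gt(nd$split$gain, 0)     # negative or zero gains never accepted
      expect_equal(nd$children$left$summary$size +
                     nd$children$right$summary$size, nd$summary$size)
      expect_equal(nd$children$left$depth, nd$depth + 1L)
    } else {
      expect_null(nd$split)
    }
  }
})

test_that("tree growth is deterministic", {
  set.seed(8)
  n <- 120
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  P <- rprob_rows(n, 3)
  t1 <- grow_tree(X, P, tree_settings(min_node = 25, method = "grow"))
  t2 <- grow_tree(X, P, tree_settings(min_node = 25, method = "grow"))
  expect_identical(jsonlite::toJSON(psicatree:::node_to_list(t1$root), digits = NA),
                   jsonlite::toJSON(psicatree:::node_to_list(t2$root), digits = NA))
})

test_that("max depth caps growth", {
  set.seed(9)
  n <- 200
  X <- data.frame(x1 = runif(n))
  P <- cbind(plogis(6 * (X$x1 - 0.5)), 1 - plogis(6 * (X$x1 - 0.5)))
  tree <- grow_tree(X, P, tree_settings(min_node = 10, max_depth = 1,
                                        method = "grow"))
  expect_lte(max(vapply(tree_nodes(tree), function(nd) nd$depth, integer(1))), 1L)
})

test_that("pruning collapses nodes without recomputation", {
  set.seed(10)
  n <- 300
  X <- data.frame(x1 = runif(n, -1, 1))
  P <- cbind(plogis(8 * X$x1), 1 - plogis(8 * X$x1))
  P <- P * 0.96 + 0.02
  P <- P / rowSums(P)
  tree <- grow_tree(X, P, tree_settings(min_node = 30, method = "grow"))
  expect_gt(n_leaves(tree), 2L)

  root_only <- prune_tree(tree, "max_leaves", 1)
  expect_equal(n_leaves(root_only), 1L)
  expect_equal(root_only$root$summary, tree$root$summary)

  unchanged <- prune_tree(tree, "min_gain", 0)
  expect_equal(n_leaves(unchanged), n_leaves(tree))

  depth1 <- prune_tree(tree, "max_depth", 1)
  expect_lte(max(vapply(tree_nodes(depth1), function(nd) nd$depth, integer(1))), 1L)
  # the retained depth-1 nodes are exactly the original ones
  orig_d1 <- Filter(function(nd) nd$depth <= 1, tree_nodes(tree))
  expect_equal(length(tree_nodes(depth1)), length(orig_d1))

  expect_error(prune_tree(tree, "zzz", 1))
})

test_that("prediction routes rows to their growth leaves", {
  set.seed(11)
  n <- 150
  X <- data.frame(x1 = runif(n, -1, 1))
  P <- cbind(plogis(8 * X$x1), 1 - plogis(8 * X$x1))
  P <- P / rowSums(P)
  tree <- grow_tree(X, P, tree_settings(min_node = 25, method = "grow"))
  pred <- predict_sets(tree, X)
  # leaf sizes from routing match the stored leaf sizes
  leaves <- Filter(function(nd) is.null(nd$children), tree_nodes(tree))
  for (leaf in leaves) {
    expect_equal(sum(pred$leaf == leaf$node_id), leaf$summary$size)
  }
  # a root-only tree returns its root summary everywhere
  r <- prune_tree(tree, "max_leaves", 1)
  pr <- predict_sets(r, X[1:7, , drop = FALSE])
  expect_equal(unique(pr$leaf), r$root$node_id)
  expect_equal(pr$pi[3, ], r$root$summary$pi)
  expect_error(predict_sets(tree, data.frame(zz = 1)), "lacks training column")
})

test_that("categorical split rules route level subsets left", {
  set.seed(12)
  n <- 200
  X <- data.frame(g = factor(sample(c("a", "b", "c", "d"), n, replace = TRUE)))
  P <- matrix(0.5, n, 2)
  P[X$g %in% c("a", "c"), 1] <- 0.95
  P[X$g %in% c("a", "c"), 2] <- 0.05
  P[!X$g %in% c("a", "c"), 1] <- 0.05
  P[!X$g %in% c("a", "c"), 2] <- 0.95
  tree <- grow_tree(X, P, tree_settings(min_node = 20, method = "grow"))
  expect_equal(tree$root$split$kind, "category")
  side <- sort(tree$root$split$left_categories)
  expect_true(identical(side, c("a", "c")) || identical(side, c("b", "d")))
  pred <- predict_sets(tree, data.frame(g = factor(c("a", "b"))))
  expect_equal(length(unique(pred$leaf)), 2L)
})
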