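test_that("constant outcomes give exactly constant predictions", {
  set.seed(1)
  X <- data.frame(x1 = runif(40, -1, 1))
  f <- fit_arm_forest(X, rep(3, 40), forest_settings(n_trees = 10, min_split = 10))
  expect_equal(predict_mean(f, X), rep(3, 40))
})

test_that("same data and seed reproduce the forest bit for bit", {
  set.seed(2)
  X <- data.frame(x1 = runif(60, -1, 1))
  y <- X$x1 + rnorm(60, 0, 0.2)
  fs <- forest_settings(n_trees = 20, min_split = 15, seed = 99)
  f1 <- fit_arm_forest(X, y, fs)
  f2 <- fit_arm_forest(X, y, fs)
  expect_identical(predict_mean(f1, X), predict_mean(f2, X))
  expect_identical(f1$inbag, f2$inbag)
})

test_that("forest recovers the levels of a step function away from the jump", {
  set.seed(3)
  n <- 400
  X <- data.frame(x1 = runif(n, -1, 1))
  y <- ifelse(X$x1 > 0, 2, -1) + rnorm(n, 0, 0.1)
  f <- fit_arm_forest(X, y, forest_settings(n_trees = 50, min_split = 40))
  q <- data.frame(x1 = c(-0.6, 0.6))
  mu <- predict_mean(f, q)
  expect_equal(mu[1], mean(y[X$x1 < -0.2]), tolerance = 0.1)
  expect_equal(mu[2], mean(y[X$x1 > 0.2]), tolerance = 0.1)
})

test_that("mean prediction equals the average of the per-tree predictions", {
  set.seed(4)
  X <- data.frame(x1 = runif(50, -1, 1), x2 = runif(50, -1, 1))
  y <- X$x1 - X$x2 + rnorm(50, 0, 0.2)
  f <- fit_arm_forest(X, y, forest_settings(n_trees = 15, min_split = 10))
  pt <- psicatree:::predict_trees(f, X)
  # independent loop over the stored trees
  manual <- rowMeans(vapply(seq_len(15), function(b) pt[, b], numeric(50)))
  expect_equal(predict_mean(f, X), manual, tolerance = 1e-12)
})

test_that("a fully grown single tree without bootstrap interpolates training points", {
  set.seed(5)
  X <- data.frame(x1 = sort(runif(20, -1, 1)))
  y <- rnorm(20)
  f <- fit_arm_forest(X, y, forest_settings(n_trees = 1, min_split = 2,
                                            min_bucket = 1, alpha_split = 1,
                                            bootstrap = FALSE))
  expect_equal(predict_mean(f, X), y, tolerance = 1e-12)
})

test_that("IJ variance matches a brute-force double loop", {
  set.seed(6)
  preds <- matrix(rnorm(5 * 30), 5, 30)           # 5 query points, 30 trees
  inbag <- matrix(rpois(12 * 30, 1), 12, 30)      # 12 training points
  fast <- psicatree:::ij_variance_core(preds, inbag)
  expect_equal(fast, oracle_ij(preds, inbag), tolerance = 1e-10)
})

test_that("IJ variance is floored when all trees agree and is permutation invariant", {
  preds <- matrix(1.5, 3, 20)
  inbag <- matrix(rpois(10 * 20, 1), 10, 20)
  expect_equal(psicatree:::ij_variance_core(preds, inbag), rep(1e-12, 3))

  set.seed(7)
  preds <- matrix(rnorm(4 * 25), 4, 25)
  inbag <- matrix(rpois(8 * 25, 1), 8, 25)
  perm <- sample(25)
  expect_equal(psicatree:::ij_variance_core(preds, inbag),
               psicatree:::ij_variance_core(preds[, perm], inbag[, perm]),
               tolerance = 1e-12)
})

test_that("fitted-forest IJ variance is near the bagged-mean variance for flat signal", {
  set.seed(8)
  n <- 300
  X <- data.frame(x1 = runif(n, -1, 1))
  y <- rnorm(n)
  f <- fit_arm_forest(X, y, forest_settings(n_trees = 100, min_split = 30,
                                            alpha_split = 1e-9, seed = 3))
  v <- ij_variance(f, X[1:5, , drop = FALSE])
  ratio <- mean(v) / (var(y) / n)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("bootstrap ensembles are reproducible and degrade gracefully to B = 1", {
  set.seed(9)
  X <- data.frame(x1 = runif(50, -1, 1))
  y <- X$x1 + rnorm(50, 0, 0.3)
  fs <- forest_settings(n_trees = 5, min_split = 10, seed = 11)
  e1 <- fit_bootstrap_ensemble(X, y, fs, B = 1)
  expect_equal(e1$B, 1L)
  expect_equal(dim(predict_ensemble(e1, X)), c(50L, 1L))

  e2 <- fit_bootstrap_ensemble(X, y, fs, B = 4)
  e3 <- fit_bootstrap_ensemble(X, y, fs, B = 4)
  expect_identical(predict_ensemble(e2, X), predict_ensemble(e3, X))
})

test_that("ensemble spread and IJ variance agree in order of magnitude", {
  set.seed(10)
  n <- 300
  X <- data.frame(x1 = runif(n, -1, 1))
  y <- sin(2 * X$x1) + rnorm(n, 0, 0.3)
  fs <- forest_settings(n_trees = 40, min_split = 30, seed = 21)
  f <- fit_arm_forest(X, y, fs)
  q <- data.frame(x1 = seq(-0.8, 0.8, by = 0.4))
  v_ij <- ij_variance(f, q, variance_floor = f$baseline_var)
  ens <- fit_bootstrap_ensemble(X, y, fs, B = 30)
  v_boot <- apply(predict_ensemble(ens, q), 1, var)
  ratio <- mean(v_boot) / mean(v_ij)
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})

test_that("pure-noise covariates leave signal predictions approximately unchanged", {
  set.seed(12)
  n <- 400
  x <- runif(n, -1, 1)
  y <- 2 * x + rnorm(n, 0, 0.2)
  fs <- forest_settings(n_trees = 60, min_split = 40, seed = 5)
  f_clean <- fit_arm_forest(data.frame(x1 = x), y, fs)
  f_noisy <- fit_arm_forest(
    data.frame(x1 = x, noise_1 = runif(n, -1, 1), noise_2 = runif(n, -1, 1)),
    y, fs)
  q_clean <- data.frame(x1 = seq(-0.8, 0.8, by = 0.2))
  q_noisy <- cbind(q_clean, noise_1 = 0, noise_2 = 0)
  expect_lt(mean((predict_mean(f_clean, q_clean) -
                    predict_mean(f_noisy, q_noisy))^2), 0.02)
})

test_that("schema violations are reported", {
  set.seed(13)
  X <- data.frame(x1 = runif(30), x2 = runif(30))
  f <- fit_arm_forest(X, rnorm(30), forest_settings(n_trees = 5, min_split = 10))
  expect_error(predict_mean(f, data.frame(x1 = 1:3)), "lacks training column")
})
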