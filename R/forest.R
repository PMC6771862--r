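# Per-treatment-arm outcome ensembles: conditional-inference regression
# forests (association-test-gated splits) with stored bootstrap inclusion
# counts for the infinitesimal jackknife, and, for the bootstrap method,
# ensembles of forests fit to resampled arm data.
#
# The base learner splits a node only when some candidate variable shows a
# significant association with the outcome (Bonferroni-adjusted over the
# mtry sampled candidates). This early stopping is what keeps the forests
# honest under pure noise: with no signal almost every tree is a single
# leaf, per-participant predictions are near-constant, and no spurious
# subgroup structure is manufactured for the tree stage to find.

#' Forest settings for per-arm outcome models
#'
#' @param n_trees trees per forest (default 100).
#' @param mtry candidate variables per split: `"all"` (= p), `"sqrt"`
#'   (= ceiling(sqrt(p))), or a positive integer.
#' @param min_split minimum node size to attempt a split. `NULL` is
#'   resolved by [fit_probabilities()] to one tenth of the arm size.
#' @param min_bucket minimum observations in a child (default 5).
#' @param alpha_split significance level of the per-node association test; a
#'   node is split only if the best candidate variable's
#'   Bonferroni-adjusted p-value is below it (default 0.005, a deliberately
#'   conservative level: with no treatment-relevant signal the arm
#'   predictions then stay essentially flat, so no spurious subgroup
#'   structure is manufactured, while genuine effects in trial-sized data
#'   give far smaller p-values). `1` disables the test (exhaustive
#'   CART-style growth).
#' @param bootstrap fit each tree on a bootstrap resample (default `TRUE`;
#'   required for the infinitesimal jackknife).
#' @param seed master seed; per-tree seeds are derived from it.
#' @return list of class `forest_settings`.
#' @export
forest_settings <- function(n_trees = 100L, mtry = "all", min_split = NULL,
                            min_bucket = 5L, alpha_split = 0.005,
                            bootstrap = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1L, min_bucket >= 1L, alpha_split > 0, alpha_split <= 1)
  if (is.character(mtry)) mtry <- match.arg(mtry, c("all", "sqrt"))
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_split = min_split, min_bucket = as.integer(min_bucket),
                 alpha_split = alpha_split, bootstrap = isTRUE(bootstrap),
                 seed = seed),
            class = "forest_settings")
}

#' @noRd
resolve_mtry <- function(mtry, p) {
  m <- switch(as.character(mtry),
              all = p,
              sqrt = ceiling(sqrt(p)),
              as.integer(mtry))
  max(1L, min(as.integer(m), p))
}

# Association p-value between one covariate and the outcome on a node.
# Numeric x: two-sided t-test of the Pearson correlation. Factor x: one-way
# ANOVA F-test. Degenerate inputs (constant x or y, too few rows) give 1.
#' @noRd
assoc_pvalue <- function(x, y) {
  n <- length(y)
  if (n < 3L) return(1)
  if (is.factor(x) || is.character(x)) {
    f <- factor(x)
    counts <- tabulate(f, nbins = nlevels(f))
    keep <- counts > 0L
    k <- sum(keep)
    if (k < 2L || n - k < 1L) return(1)
    sums <- vapply(split(y, f), sum, numeric(1))[keep]
    gmeans <- sums / counts[keep]
    ssb <- sum(counts[keep] * (gmeans - mean(y))^2)
    ssw <- sum((y - ave(y, f))^2)
    if (ssw <= 0) return(if (ssb > 0) 0 else 1)
    f_stat <- (ssb / (k - 1)) / (ssw / (n - k))
    stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  } else {
    sx <- x - mean(x)
    sy <- y - mean(y)
    den <- sqrt(sum(sx^2) * sum(sy^2))
    if (den <= 0) return(1)
    r <- min(1, max(-1, sum(sx * sy) / den))
    if (abs(r) >= 1) return(0)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), n - 2)
  }
}

# Best sum-of-squares-reducing cut of a numeric variable; children must hold
# at least min_bucket rows. Returns NULL or list(threshold, left = logical).
#' @noRd
best_cut_numeric <- function(x, y, min_bucket) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cy <- cumsum(ys)
  cy2 <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  valid <- i >= min_bucket & (n - i) >= min_bucket & xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  sse <- (cy2[i] - cy[i]^2 / i) +
    ((cy2[n] - cy2[i]) - (cy[n] - cy[i])^2 / (n - i))
  best <- i[which.min(sse)]
  thr <- (xs[best] + xs[best + 1L]) / 2
  list(threshold = thr, left = x <= thr)
}

# Best cut of a factor: levels ordered by mean outcome, then treated as
# ordered (exact for squared-error loss). Returns NULL or
# list(left_levels, left).
#' @noRd
best_cut_factor <- function(x, y, min_bucket) {
  f <- droplevels(factor(x))
  k <- nlevels(f)
  if (k < 2L) return(NULL)
  gmean <- vapply(split(y, f), mean, numeric(1))
  lev_ord <- levels(f)[order(gmean, seq_len(k))]
  z <- match(as.character(f), lev_ord)   # rank of each row's level
  best <- NULL
  best_sse <- Inf
  for (cut in seq_len(k - 1L)) {
    left <- z <= cut
    nl <- sum(left)
    if (nl < min_bucket || length(y) - nl < min_bucket) next
    yl <- y[left]; yr <- y[!left]
    sse <- sum(yl^2) - sum(yl)^2 / nl + sum(yr^2) - sum(yr)^2 / length(yr)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(left_levels = lev_ord[seq_len(cut)], left = left)
    }
  }
  best
}

# Grow one conditional-inference regression tree on rows idx (a bootstrap
# multiset). Returns a flat list of nodes; node 1 is the root.
#' @noRd
grow_ci_tree <- function(cols, y, idx, mtry, min_split, min_bucket,
                         alpha_split) {
  p <- length(cols)
  nodes <- list()
  rec <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(leaf = TRUE, value = mean(y[idx]), n = length(idx))
    n_i <- length(idx)
    if (n_i < min_split || n_i < 2L * min_bucket) return(id)
    yi <- y[idx]
    if (stats::var(yi) <= 0) return(id)
    vars <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    # association tests on the distinct underlying observations: bootstrap
    # duplicates are pseudo-replicates and would inflate significance
    uidx <- unique(idx)
    pvals <- vapply(vars, function(j) assoc_pvalue(cols[[j]][uidx], y[uidx]),
                    numeric(1))
    j_best <- vars[which.min(pvals)]
    if (min(1, min(pvals) * length(vars)) > alpha_split) return(id)
    xj <- cols[[j_best]][idx]
    cut <- if (is.factor(xj) || is.character(xj)) {
      best_cut_factor(xj, yi, min_bucket)
    } else {
      best_cut_numeric(xj, yi, min_bucket)
    }
    if (is.null(cut)) return(id)
    left_id <- rec(idx[cut$left])
    right_id <- rec(idx[!cut$left])
    nodes[[id]] <<- list(leaf = FALSE, var = j_best,
                         kind = if (is.null(cut$threshold)) "factor" else "numeric",
                         threshold = cut$threshold,
                         left_levels = cut$left_levels,
                         left = left_id, right = right_id, n = n_i)
    id
  }
  rec(idx)
  nodes
}

# Predictions of one tree at the query columns.
#' @noRd
predict_ci_tree <- function(nodes, cols, n_query) {
  preds <- numeric(n_query)
  rec <- function(id, qidx) {
    node <- nodes[[id]]
    if (node$leaf) {
      preds[qidx] <<- node$value
      return(invisible())
    }
    x <- cols[[node$var]][qidx]
    left <- if (node$kind == "numeric") {
      x <= node$threshold
    } else {
      as.character(x) %in% node$left_levels
    }
    if (any(left)) rec(node$left, qidx[left])
    if (any(!left)) rec(node$right, qidx[!left])
  }
  if (n_query > 0L) rec(1L, seq_len(n_query))
  preds
}

#' @noRd
as_columns <- function(X) {
  lapply(X, function(z) if (is.character(z)) factor(z) else z)
}

#' Fit a conditional-inference regression forest to one treatment arm
#'
#' Grows `n_trees` regression trees, each (by default) on a bootstrap
#' resample of the arm's data with the per-tree inclusion counts kept for
#' the infinitesimal jackknife. At each node, `mtry` randomly sampled
#' covariates are tested for association with the outcome (correlation
#' t-test for numeric covariates, one-way ANOVA F-test for categorical
#' ones); the node is split on the most significant variable only if its
#' Bonferroni-adjusted p-value is below `alpha_split`, at the
#' sum-of-squares-minimizing cut point. Nodes without a significant
#' candidate become leaves, so forests fit to pure noise collapse to
#' near-constant predictors.
#'
#' @param X covariate data frame for the arm.
#' @param y numeric outcomes for the arm.
#' @param settings a [forest_settings()] object with `min_split` resolved.
#' @param label optional arm label, carried for printing.
#' @return object of class `arm_forest`.
#' @export
fit_arm_forest <- function(X, y, settings = forest_settings(min_split = 5L),
                           label = NULL) {
  stopifnot(is.data.frame(X), nrow(X) == length(y), ncol(X) >= 1L)
  n <- nrow(X)
  min_split <- settings$min_split
  if (is.null(min_split)) min_split <- max(5L, ceiling(n / 10))
  cols <- as_columns(X)
  mtry <- resolve_mtry(settings$mtry, ncol(X))
  trees <- vector("list", settings$n_trees)
  inbag <- matrix(0L, n, settings$n_trees)
  for (b in seq_len(settings$n_trees)) {
    set.seed(derive_seed(settings$seed, stream = 1L, index = b))
    idx <- if (settings$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    inbag[, b] <- tabulate(idx, nbins = n)
    trees[[b]] <- grow_ci_tree(cols, y, idx, mtry, min_split,
                               settings$min_bucket, settings$alpha_split)
  }
  structure(
    list(trees = trees, n = n, p = ncol(X), inbag = inbag,
         # sampling variance of the arm's plain bagged mean: a lower bound
         # used by the sampling step to stabilize noisy per-row IJ estimates
         baseline_var = stats::var(y) / n,
         settings = settings, label = label,
         schema = vapply(X, function(z) class(z)[1L], character(1))),
    class = "arm_forest"
  )
}

#' @export
print.arm_forest <- function(x, ...) {
  n_nodes <- vapply(x$trees, length, integer(1))
  cat(sprintf("Arm forest%s: n = %d, p = %d, %d trees (%.1f nodes/tree)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$n, x$p, length(x$trees), mean(n_nodes)))
  invisible(x)
}

#' @noRd
check_schema <- function(forest, X) {
  want <- names(forest$schema)
  missing <- setdiff(want, names(X))
  if (length(missing)) {
    stop(sprintf("query table lacks training column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  X[, want, drop = FALSE]
}

#' Per-tree predictions (n_query x n_trees)
#' @noRd
predict_trees <- function(forest, X) {
  X <- check_schema(forest, X)
  cols <- as_columns(X)
  n <- nrow(X)
  out <- matrix(0, n, length(forest$trees))
  for (b in seq_along(forest$trees)) {
    out[, b] <- predict_ci_tree(forest$trees[[b]], cols, n)
  }
  out
}

#' Mean forest prediction
#'
#' Average of the per-tree predictions at each query row.
#'
#' @param forest an [fit_arm_forest()] object.
#' @param X query covariate table (same schema as training).
#' @return numeric vector, one prediction per row of `X`.
#' @export
predict_mean <- function(forest, X) {
  stopifnot(inherits(forest, "arm_forest"))
  rowMeans(predict_trees(forest, X))
}

#' Core infinitesimal-jackknife computation from per-tree predictions and
#' inclusion counts. Kept separate from the forest object so it can be
#' checked against a brute-force double loop.
#' @param preds n_query x B matrix of per-tree predictions.
#' @param inbag n_train x B matrix of bootstrap inclusion counts.
#' @noRd
ij_variance_core <- function(preds, inbag, variance_floor = 1e-12) {
  B <- ncol(preds)
  stopifnot(ncol(inbag) == B, B >= 2L)
  centered <- preds - rowMeans(preds)              # t_b(x) - tbar(x)
  # Cov_i(x) = (1/B) sum_b (N_{b,i} - 1) (t_b(x) - tbar(x));
  # the "-1" is immaterial because the t_b are centered.
  cov_mat <- (inbag %*% t(centered)) / B           # n_train x n_query
  raw <- colSums(cov_mat^2)
  s2 <- rowMeans(centered^2)                       # per-tree prediction variance
  pmax(raw - nrow(inbag) / B * s2, variance_floor)
}

#' Bias-corrected infinitesimal-jackknife variance of forest predictions
#'
#' Estimates the sampling variance of the mean forest prediction at each
#' query row from the covariance between bootstrap inclusion counts and
#' per-tree predictions, with the Monte Carlo bias correction
#' `(n_k / B) * s2(x)` subtracted (s2 = variance of the per-tree
#' predictions). Results are floored at `variance_floor` so downstream
#' normal sampling is always well defined.
#'
#' @inheritParams predict_mean
#' @param variance_floor lower bound for the returned variance (default
#'   1e-12).
#' @return numeric vector of non-negative variances.
#' @export
ij_variance <- function(forest, X, variance_floor = 1e-12) {
  stopifnot(inherits(forest, "arm_forest"))
  if (is.null(forest$inbag)) stop("forest was fitted without inclusion counts")
  if (!forest$settings$bootstrap) {
    stop("infinitesimal jackknife requires a bootstrap-resampled forest")
  }
  ij_variance_core(predict_trees(forest, X), forest$inbag, variance_floor)
}

#' Fit a bootstrap ensemble of forests to one treatment arm
#'
#' Draws `B` bootstrap resamples of the arm's data and fits one forest to
#' each; the ensemble members' predictions are the joint outcome samples of
#' the bootstrap probability-estimation method. Each member gets its own
#' seed derived from the master seed.
#'
#' @inheritParams fit_arm_forest
#' @param B number of ensemble members (default 500).
#' @return object of class `bootstrap_ensemble`.
#' @export
fit_bootstrap_ensemble <- function(X, y, settings = forest_settings(min_split = 5L),
                                   B = 500L, label = NULL) {
  stopifnot(B >= 1L, is.data.frame(X), nrow(X) == length(y))
  n <- nrow(X)
  models <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(settings$seed, stream = 7L, index = b))
    idx <- sample.int(n, n, replace = TRUE)
    member_settings <- settings
    member_settings$seed <- derive_seed(settings$seed, stream = 8L, index = b)
    models[[b]] <- fit_arm_forest(X[idx, , drop = FALSE], y[idx],
                                  member_settings, label = label)
  }
  structure(list(models = models, B = as.integer(B), label = label,
                 settings = settings),
            class = "bootstrap_ensemble")
}

#' Member predictions of a bootstrap ensemble (n_query x B)
#'
#' @param ensemble a [fit_bootstrap_ensemble()] object.
#' @param X query covariate table.
#' @return matrix with one column per ensemble member.
#' @export
predict_ensemble <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  out <- matrix(0, nrow(X), ensemble$B)
  for (b in seq_len(ensemble$B)) out[, b] <- predict_mean(ensemble$models[[b]], X)
  out
}
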