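# Growing the subgroup tree on (X_i, P_i): split search by information gain
# on the misassignment-cost loss, optional chi-square pre-pruning gate,
# pruning utilities and leaf labelling.

#' Tree-growing settings
#'
#' @param alpha risk level for the useless/potential split and the
#'   chi-square gate (default 0.05).
#' @param min_node minimum observations for a node to be split; `NULL`
#'   resolves to `ceiling(n/5)` at fit time.
#' @param max_depth optional depth cap (root has depth 0); default unlimited.
#' @param method `"preprune"` gates every split on a chi-square test of the
#'   children's probability distributions (recommended); `"grow"` accepts any
#'   positive-gain split and relies on [prune_tree()] afterwards.
#' @param costs `m x m` misassignment cost matrix; `NULL` means zero-one
#'   costs.
#' @param gate_all_candidates if `TRUE` (default) the gated gain is computed
#'   for every candidate split; if `FALSE` only the best-by-gain candidate is
#'   gated (faster, may refuse a split another candidate would have passed).
#' @param max_exhaustive_categories largest number of factor levels for
#'   which all binary partitions are enumerated; above it, levels are ordered
#'   by their mean first-arm probability and only order-respecting splits are
#'   tried.
#' @return list of class `tree_settings`.
#' @export
tree_settings <- function(alpha = 0.05, min_node = NULL, max_depth = Inf,
                          method = c("preprune", "grow"), costs = NULL,
                          gate_all_candidates = TRUE,
                          max_exhaustive_categories = 10L) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(min_node)) stopifnot(min_node >= 2L)
  structure(list(alpha = alpha, min_node = min_node, max_depth = max_depth,
                 method = match.arg(method), costs = costs,
                 gate_all_candidates = isTRUE(gate_all_candidates),
                 max_exhaustive_categories = as.integer(max_exhaustive_categories)),
            class = "tree_settings")
}

#' Aggregate per-row best-treatment probabilities over a node
#'
#' Column means of the node's probability rows; sums to 1.
#'
#' @param P matrix of probability rows belonging to the node.
#' @return numeric probability vector of length m.
#' @export
aggregate_probabilities <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 1L) stop("empty node")
  check_prob_vector(colMeans(P), what = "aggregated probabilities")
}

# Loss from a node's aggregated probabilities and size. For zero-one costs
# this is |D| * sum_k pi_k (1 - pihat_k); for a general cost matrix the
# per-row sum of the misassignment cost factorises through the aggregate to
# |D| * sum_k sum_{j in Tp, j != k} c_kj pihat_j pi_k.
#' @noRd
loss_from_agg <- function(pi, size, costs = NULL, alpha = 0.05) {
  sets <- potential_sets(pi, alpha)
  pihat <- truncated_probabilities(pi, sets$potential)
  if (is.null(costs)) {
    return(size * sum(pi * (1 - pihat)))
  }
  m <- length(pi)
  acc <- 0
  for (k in seq_len(m)) {
    for (j in sets$potential) {
      if (j != k) acc <- acc + costs[k, j] * pihat[j] * pi[k]
    }
  }
  size * acc
}

#' Misassignment-cost loss of a node
#'
#' The expected cost of assigning the node's participants according to the
#' node's truncated probabilities when each participant's truly best
#' treatment follows their own probability row. With `costs = NULL` the
#' zero-one closed form `|D| * sum_k pi_k(D) (1 - pihat_k(D))` is used; with
#' an explicit cost matrix the literal per-row triple sum
#' `sum_i sum_k sum_{j in Tp, j != k} c_kj pihat_j(D) pi_k(X_i)` is
#' evaluated. The two agree identically when the explicit matrix is
#' zero-one.
#'
#' @param P matrix of probability rows in the node.
#' @param costs optional `m x m` cost matrix (`NULL` = zero-one closed form).
#' @param alpha risk level defining the potential set.
#' @return non-negative scalar loss.
#' @export
node_loss <- function(P, costs = NULL, alpha = 0.05) {
  P <- as.matrix(P)
  n <- nrow(P)
  m <- ncol(P)
  pi <- aggregate_probabilities(P)
  if (is.null(costs)) return(loss_from_agg(pi, n, NULL, alpha))
  check_cost_matrix(costs, m)
  sets <- potential_sets(pi, alpha)
  pihat <- truncated_probabilities(pi, sets$potential)
  acc <- 0
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      for (j in sets$potential) {
        if (j != k) acc <- acc + costs[k, j] * pihat[j] * P[i, k]
      }
    }
  }
  acc
}

#' Information gain of a candidate split
#'
#' `g = L(parent) - L(left) - L(right)`; positive when the split reduces the
#' total misassignment cost.
#'
#' @param P_parent,P_left,P_right probability-row matrices of the parent node
#'   and the two children (children must partition the parent's rows).
#' @inheritParams node_loss
#' @return scalar gain.
#' @export
information_gain <- function(P_parent, P_left, P_right, costs = NULL,
                             alpha = 0.05) {
  node_loss(P_parent, costs, alpha) -
    node_loss(P_left, costs, alpha) - node_loss(P_right, costs, alpha)
}

# Pearson chi-square on a real-valued m x 2 count table. Rows that are zero
# in both columns are dropped; degenerate tables (fewer than 2 rows left, or
# a zero column total) yield a failed gate rather than an error.
#' @noRd
pearson_chisq <- function(counts) {
  keep <- rowSums(counts) > 0
  tab <- counts[keep, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) <= 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Pooled standard deviation of all m*|D| per-row probabilities of a child,
# from the node size and the sum of squared entries (the pooled mean is
# always 1/m because rows sum to 1).
#' @noRd
pooled_sd_from_sums <- function(size, m, sumsq) {
  N <- size * m
  if (N < 2L) return(NA_real_)
  v <- (sumsq - N * (1 / m)^2) / (N - 1)
  sqrt(max(v, 0))
}

#' @noRd
omega_factor <- function(sd_j, sd_cap = 0.005) {
  if (is.na(sd_j)) return(NA_real_)
  (1 / sqrt(12)) / max(sd_j, sd_cap)
}

#' Chi-square gate comparing the children of a candidate split
#'
#' Converts each child's aggregated probabilities into pseudo-counts
#' `n_kj = pi_k(D_j) * |D_j| * omega_j`, where the inflation factor
#' `omega_j` is the standard deviation of U\[0,1\] (`1/sqrt(12)`) divided by
#' the pooled standard deviation of all the child's per-row probabilities
#' (children whose probabilities have low spread are upweighted as more
#' confident; the sd is floored at `sd_cap` so near-degenerate children do
#' not overflow). A Pearson chi-square test on the resulting `m x 2` table
#' passes the gate when its p-value is below `alpha`.
#'
#' @param P_left,P_right probability-row matrices of the two children.
#' @param alpha risk level.
#' @param sd_cap lower bound on the child standard deviation (default
#'   0.005).
#' @return list with `counts`, `omegas`, `statistic`, `p_value` and logical
#'   `gate` (`TRUE` = children differ significantly, split allowed).
#' @export
chi_square_gate <- function(P_left, P_right, alpha = 0.05, sd_cap = 0.005) {
  P_left <- as.matrix(P_left)
  P_right <- as.matrix(P_right)
  m <- ncol(P_left)
  stopifnot(ncol(P_right) == m, nrow(P_left) >= 1L, nrow(P_right) >= 1L)
  sizes <- c(nrow(P_left), nrow(P_right))
  omegas <- c(
    omega_factor(pooled_sd_from_sums(sizes[1L], m, sum(P_left^2)), sd_cap),
    omega_factor(pooled_sd_from_sums(sizes[2L], m, sum(P_right^2)), sd_cap)
  )
  if (anyNA(omegas)) {
    return(list(counts = NULL, omegas = omegas, statistic = NA_real_,
                p_value = 1, gate = FALSE))
  }
  counts <- cbind(colMeans(P_left) * sizes[1L] * omegas[1L],
                  colMeans(P_right) * sizes[2L] * omegas[2L])
  test <- pearson_chisq(counts)
  list(counts = counts, omegas = omegas, statistic = test$statistic,
       p_value = test$p_value,
       gate = is.finite(test$p_value) && test$p_value < alpha)
}

# Gate computation from cached aggregates (same math as chi_square_gate but
# fed by cumulative sums inside the split search).
#' @noRd
gate_from_agg <- function(pi_l, n_l, sumsq_l, pi_r, n_r, sumsq_r, m, alpha,
                          sd_cap = 0.005) {
  omegas <- c(omega_factor(pooled_sd_from_sums(n_l, m, sumsq_l), sd_cap),
              omega_factor(pooled_sd_from_sums(n_r, m, sumsq_r), sd_cap))
  if (anyNA(omegas)) return(list(gate = FALSE, p_value = 1))
  counts <- cbind(pi_l * n_l * omegas[1L], pi_r * n_r * omegas[2L])
  test <- pearson_chisq(counts)
  list(gate = is.finite(test$p_value) && test$p_value < alpha,
       p_value = test$p_value)
}

# Enumerate candidate splits of one variable and return the local best.
# `x` is the variable column (numeric or factor), `P` the node's probability
# rows, `parent_loss` L(node). Returns NULL or a list describing the best
# candidate by effective gain.
#' @noRd
best_candidate_for_variable <- function(x, P, parent_loss, settings) {
  n <- nrow(P)
  m <- ncol(P)
  if (n < 2L) return(NULL)
  gated <- settings$method == "preprune" && settings$gate_all_candidates

  eval_candidate <- function(left_idx) {
    n_l <- length(left_idx)
    n_r <- n - n_l
    if (n_l == 0L || n_r == 0L) return(NULL)
    P_l <- P[left_idx, , drop = FALSE]
    P_r <- P[-left_idx, , drop = FALSE]
    pi_l <- colSums(P_l) / n_l
    pi_r <- colSums(P_r) / n_r
    g <- parent_loss -
      loss_from_agg(pi_l, n_l, settings$costs, settings$alpha) -
      loss_from_agg(pi_r, n_r, settings$costs, settings$alpha)
    res <- list(gain = g, gain_eff = g, gate_p = NA_real_)
    if (gated) {
      gt <- gate_from_agg(pi_l, n_l, sum(P_l^2), pi_r, n_r, sum(P_r^2),
                          m, settings$alpha)
      res$gain_eff <- g * as.numeric(gt$gate)
      res$gate_p <- gt$p_value
    }
    res
  }

  best <- NULL
  consider <- function(cand, rule) {
    if (is.null(cand)) return()
    if (is.null(best) || cand$gain_eff > best$gain_eff) {
      best <<- c(cand, rule)
    }
  }

  if (is.factor(x)) {
    lev <- levels(droplevels(x))
    c_lev <- length(lev)
    if (c_lev < 2L) return(NULL)
    if (c_lev <= settings$max_exhaustive_categories) {
      # all 2^(c-1) - 1 binary partitions: fix the first level to the left
      for (mask in seq_len(2^(c_lev - 1L)) - 1L) {
        bits <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(c_lev - 1L) - 1L))))
        if (all(bits)) next
        left_lev <- lev[bits]
        consider(eval_candidate(which(x %in% left_lev)),
                 list(kind = "category", left_categories = left_lev))
      }
    } else {
      # heuristic: order levels by mean first-arm probability
      means <- vapply(lev, function(l) mean(P[x == l, 1L]), numeric(1))
      ord_lev <- lev[order(means, seq_along(lev))]
      for (cut in seq_len(c_lev - 1L)) {
        left_lev <- ord_lev[seq_len(cut)]
        consider(eval_candidate(which(x %in% left_lev)),
                 list(kind = "category", left_categories = left_lev))
      }
    }
  } else {
    ord <- order(x)
    xs <- x[ord]
    Ps <- P[ord, , drop = FALSE]
    cum <- apply(Ps, 2L, cumsum)
    cumsq <- cumsum(rowSums(Ps^2))
    tot <- cum[n, ]
    totsq <- cumsq[n]
    boundaries <- which(xs[-n] < xs[-1L])
    for (i in boundaries) {
      n_l <- i
      n_r <- n - i
      pi_l <- cum[i, ] / n_l
      pi_r <- (tot - cum[i, ]) / n_r
      g <- parent_loss -
        loss_from_agg(pi_l, n_l, settings$costs, settings$alpha) -
        loss_from_agg(pi_r, n_r, settings$costs, settings$alpha)
      cand <- list(gain = g, gain_eff = g, gate_p = NA_real_)
      if (gated) {
        gt <- gate_from_agg(pi_l, n_l, cumsq[i], pi_r, n_r, totsq - cumsq[i],
                            m, settings$alpha)
        cand$gain_eff <- g * as.numeric(gt$gate)
        cand$gate_p <- gt$p_value
      }
      consider(cand, list(kind = "numeric",
                          threshold = (xs[i] + xs[i + 1L]) / 2))
    }
  }
  best
}

#' Search for the best split of a node
#'
#' Evaluates every admissible candidate split: for numeric variables the
#' midpoints between consecutive distinct sorted values, for categorical
#' variables all binary level partitions (or order-based partitions above
#' `max_exhaustive_categories` levels). Candidates are ranked by information
#' gain (`method = "grow"`) or by the gated gain `g * G` from the chi-square
#' test (`method = "preprune"`). Ties go to the lowest variable index, then
#' the lowest threshold.
#'
#' @param X covariate data frame of the node's rows.
#' @param P matrix of the node's probability rows.
#' @param settings a [tree_settings()] object.
#' @return `NULL` if no candidate has positive (gated) gain, else a list
#'   with `variable`, `var_index`, `kind`, `threshold` or `left_categories`,
#'   `gain`, `gain_eff`, `gate_p`.
#' @export
best_split_search <- function(X, P, settings = tree_settings()) {
  P <- as.matrix(P)
  stopifnot(nrow(X) == nrow(P))
  parent_loss <- loss_from_agg(aggregate_probabilities(P), nrow(P),
                               settings$costs, settings$alpha)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- best_candidate_for_variable(X[[j]], P, parent_loss, settings)
    if (is.null(cand)) next
    if (is.null(best) || cand$gain_eff > best$gain_eff) {
      cand$variable <- names(X)[j]
      cand$var_index <- j
      best <- cand
    }
  }
  if (is.null(best) || best$gain_eff <= 0) return(NULL)
  if (settings$method == "preprune" && !settings$gate_all_candidates) {
    # fast mode: gate only the winner by plain gain
    left <- split_goes_left(X[[best$var_index]], best)
    gt <- chi_square_gate(P[left, , drop = FALSE], P[!left, , drop = FALSE],
                          settings$alpha)
    best$gate_p <- gt$p_value
    if (!gt$gate) return(NULL)
  }
  best
}

#' @noRd
split_goes_left <- function(x, rule) {
  if (rule$kind == "numeric") {
    as.numeric(x) <= rule$threshold
  } else {
    as.character(x) %in% rule$left_categories
  }
}

#' @noRd
summarize_node <- function(P, treatments, costs, alpha) {
  pi <- aggregate_probabilities(P)
  sets <- potential_sets(pi, alpha)
  pihat <- truncated_probabilities(pi, sets$potential)
  list(size = nrow(P), pi = stats::setNames(pi, treatments),
       useless = treatments[sets$useless],
       potential = treatments[sets$potential],
       pi_hat = stats::setNames(pihat, treatments),
       loss = loss_from_agg(pi, nrow(P), costs, alpha))
}

#' Grow a subgroup-identification tree on best-treatment probabilities
#'
#' Recursively partitions the covariate space, at each node choosing the
#' split that maximizes the information gain of the misassignment-cost loss
#' (gated by the chi-square test when `method = "preprune"`). A node is split
#' only while it holds at least `min_node` observations, is shallower than
#' `max_depth`, and some candidate has strictly positive (gated) gain. Every
#' node, internal or leaf, carries its size, aggregated probabilities,
#' useless/potential treatment sets, truncated probabilities and loss.
#'
#' @param trial a [validate_trial()] object (or a bare covariate data
#'   frame).
#' @param P `n x m` best-probability table aligned with the trial rows.
#' @param settings a [tree_settings()] object; a `NULL` `min_node` resolves
#'   to `ceiling(n/5)`.
#' @return object of class `psica_tree`.
#' @export
grow_tree <- function(trial, P, settings = tree_settings()) {
  X <- if (inherits(trial, "trial_data")) trial$X else as.data.frame(trial)
  P <- as.matrix(P)
  stopifnot(nrow(X) == nrow(P))
  treatments <- if (inherits(trial, "trial_data")) {
    trial$treatments
  } else if (!is.null(colnames(P))) {
    colnames(P)
  } else {
    paste0("tau", seq_len(ncol(P)))
  }
  if (!is.null(settings$costs)) check_cost_matrix(settings$costs, ncol(P))
  if (is.null(settings$min_node)) settings$min_node <- max(2L, ceiling(nrow(P) / 5))

  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  counter$gate_rejections <- 0L

  build <- function(idx, depth) {
    node <- list(
      node_id = counter$next_id, depth = depth,
      summary = summarize_node(P[idx, , drop = FALSE], treatments,
                               settings$costs, settings$alpha),
      split = NULL, children = NULL
    )
    counter$next_id <- counter$next_id + 1L
    if (length(idx) >= settings$min_node && depth < settings$max_depth) {
      rule <- best_split_search(X[idx, , drop = FALSE],
                                P[idx, , drop = FALSE], settings)
      if (!is.null(rule)) {
        left <- split_goes_left(X[idx, , drop = FALSE][[rule$var_index]], rule)
        node$split <- rule
        node$children <- list(
          left = build(idx[left], depth + 1L),
          right = build(idx[!left], depth + 1L)
        )
      } else {
        counter$gate_rejections <- counter$gate_rejections + 1L
      }
    }
    node
  }

  root <- build(seq_len(nrow(P)), 0L)
  structure(
    list(root = root, treatments = treatments, settings = settings,
         n = nrow(P), schema = vapply(X, function(z) class(z)[1L], character(1)),
         gate_rejections = counter$gate_rejections),
    class = "psica_tree"
  )
}

#' Flat list of all nodes of a tree (preorder)
#' @param tree a `psica_tree`.
#' @return list of node lists.
#' @export
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    if (!is.null(node$children)) {
      walk(node$children$left)
      walk(node$children$right)
    }
  }
  walk(tree$root)
  out
}

#' Number of leaves of a tree
#' @param tree a `psica_tree`.
#' @export
n_leaves <- function(tree) {
  sum(vapply(tree_nodes(tree), function(nd) is.null(nd$children), logical(1)))
}

#' Prune a fitted tree
#'
#' Collapsing an internal node needs no recomputation: its stored summary
#' already describes the merged region.
#'
#' @param tree a `psica_tree`.
#' @param criterion `"max_depth"` (drop all splits below a depth),
#'   `"min_gain"` (collapse splits whose gain is below `value`), or
#'   `"max_leaves"` (repeatedly collapse the lowest-gain collapsible split
#'   until at most `value` leaves remain).
#' @param value criterion value.
#' @return the pruned `psica_tree`.
#' @export
prune_tree <- function(tree, criterion = c("max_depth", "min_gain", "max_leaves"),
                       value) {
  criterion <- match.arg(criterion)
  collapse <- function(node) { node$split <- NULL; node$children <- NULL; node }

  if (criterion == "max_depth") {
    walk <- function(node) {
      if (!is.null(node$children)) {
        if (node$depth >= value) return(collapse(node))
        node$children$left <- walk(node$children$left)
        node$children$right <- walk(node$children$right)
      }
      node
    }
    tree$root <- walk(tree$root)
  } else if (criterion == "min_gain") {
    walk <- function(node) {
      if (!is.null(node$children)) {
        if (node$split$gain < value) return(collapse(node))
        node$children$left <- walk(node$children$left)
        node$children$right <- walk(node$children$right)
      }
      node
    }
    tree$root <- walk(tree$root)
  } else {
    stopifnot(value >= 1)
    while (n_leaves(tree) > value) {
      # find the collapsible internal node (both children leaves) of least gain
      best_id <- NA_integer_
      best_gain <- Inf
      for (nd in tree_nodes(tree)) {
        if (!is.null(nd$children) &&
            is.null(nd$children$left$children) &&
            is.null(nd$children$right$children) &&
            nd$split$gain < best_gain) {
          best_gain <- nd$split$gain
          best_id <- nd$node_id
        }
      }
      walk <- function(node) {
        if (!is.null(node$children)) {
          if (node$node_id == best_id) return(collapse(node))
          node$children$left <- walk(node$children$left)
          node$children$right <- walk(node$children$right)
        }
        node
      }
      tree$root <- walk(tree$root)
    }
  }
  tree
}

#' Route query rows to leaves and return their treatment summaries
#'
#' @param tree a `psica_tree`.
#' @param X query covariate table with the training columns.
#' @return list with `leaf` (node ids), `potential` (list of label vectors),
#'   `useless` (list), `pi` and `pi_hat` (`n x m` matrices).
#' @export
predict_sets <- function(tree, X) {
  X <- as.data.frame(X)
  missing <- setdiff(names(tree$schema), names(X))
  if (length(missing)) {
    stop(sprintf("query table lacks training column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(X)
  m <- length(tree$treatments)
  leaf <- integer(n)
  pi <- matrix(0, n, m, dimnames = list(NULL, tree$treatments))
  pi_hat <- pi
  potential <- vector("list", n)
  useless <- vector("list", n)
  route <- function(node, idx) {
    if (is.null(node$children)) {
      leaf[idx] <<- node$node_id
      pi[idx, ] <<- matrix(node$summary$pi, length(idx), m, byrow = TRUE)
      pi_hat[idx, ] <<- matrix(node$summary$pi_hat, length(idx), m, byrow = TRUE)
      for (i in idx) {
        potential[[i]] <<- node$summary$potential
        useless[[i]] <<- node$summary$useless
      }
      return(invisible())
    }
    left <- split_goes_left(X[idx, node$split$variable], node$split)
    if (any(left)) route(node$children$left, idx[left])
    if (any(!left)) route(node$children$right, idx[!left])
  }
  if (n > 0L) route(tree$root, seq_len(n))
  list(leaf = leaf, potential = potential, useless = useless,
       pi = pi, pi_hat = pi_hat)
}

#' @export
print.psica_tree <- function(x, digits = 2L, ...) {
  cat(sprintf("Subgroup tree: n = %d, %d leaves, treatments: %s\n",
              x$n, n_leaves(x), paste(x$treatments, collapse = ", ")))
  fmt_rule <- function(split) {
    if (is.null(split)) return("root")
    if (split$kind == "numeric") {
      sprintf("%s <= %.4g", split$variable, split$threshold)
    } else {
      sprintf("%s in {%s}", split$variable,
              paste(split$left_categories, collapse = ","))
    }
  }
  walk <- function(node, prefix, rule_txt) {
    s <- node$summary
    cat(sprintf("%s%s  n=%d  Tp={%s}  pi=(%s)%s\n", prefix, rule_txt, s$size,
                paste(s$potential, collapse = ","),
                paste(format(round(s$pi, digits), nsmall = digits),
                      collapse = ", "),
                if (is.null(node$children)) " *" else ""))
    if (!is.null(node$children)) {
      walk(node$children$left, paste0(prefix, "  "), fmt_rule(node$split))
      neg <- if (node$split$kind == "numeric") {
        sprintf("%s > %.4g", node$split$variable, node$split$threshold)
      } else {
        sprintf("%s not in {%s}", node$split$variable,
                paste(node$split$left_categories, collapse = ","))
      }
      walk(node$children$right, paste0(prefix, "  "), neg)
    }
  }
  walk(x$root, "", "root")
  invisible(x)
}
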