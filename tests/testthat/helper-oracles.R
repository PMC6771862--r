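# Shared fixtures and independent oracle implementations used by the tests.
# The oracles deliberately re-derive every quantity from first principles
# (their own sorting, their own loops) so they share no code path with the
# package internals they check.

# random probability rows via normalized Gamma draws
rprob_rows <- function(n, m) {
  g <- matrix(stats::rgamma(n * m, shape = 1), n, m)
  g / rowSums(g)
}

# small three-arm trial fixture with a clean covariate signal
make_toy_trial <- function(n = 90, seed = 42) {
  set.seed(seed)
  x <- runif(n, -1, 1)
  t <- factor(sample(c("A", "B", "C"), n, replace = TRUE),
              levels = c("A", "B", "C"))
  mu <- cbind(-x, x, 0)[cbind(seq_len(n), as.integer(t))]
  validate_trial(data.frame(x1 = x, y = mu + rnorm(n, 0, 0.1), t = t))
}

# ---- loss oracle: literal Eq.-style evaluation with its own set algebra ----

oracle_sets <- function(pi, alpha) {
  m <- length(pi)
  ord <- order(pi, seq_len(m))
  useless <- integer(0)
  acc <- 0
  for (k in ord) {
    if (acc + pi[k] <= alpha) {
      acc <- acc + pi[k]
      useless <- c(useless, k)
    } else break
  }
  list(useless = sort(useless), potential = sort(setdiff(seq_len(m), useless)))
}

oracle_loss <- function(P, alpha = 0.05, costs = NULL) {
  m <- ncol(P)
  if (is.null(costs)) costs <- matrix(1, m, m) - diag(m)
  pi <- colSums(P) / nrow(P)
  sets <- oracle_sets(pi, alpha)
  pihat <- numeric(m)
  pihat[sets$potential] <- pi[sets$potential] / sum(pi[sets$potential])
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (k in seq_len(m)) {
      for (j in sets$potential) {
        if (j != k) total <- total + costs[k, j] * pihat[j] * P[i, k]
      }
    }
  }
  total
}

# ---- exhaustive split-search oracle --------------------------------------

oracle_candidates <- function(x) {
  if (is.factor(x)) {
    lev <- levels(droplevels(x))
    cands <- list()
    if (length(lev) >= 2L) {
      for (mask in 0:(2^(length(lev) - 1L) - 1L)) {
        bits <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_along(lev[-1]) - 1L))))
        if (all(bits)) next
        cands[[length(cands) + 1L]] <- list(kind = "category",
                                            left_categories = lev[bits])
      }
    }
    cands
  } else {
    ux <- sort(unique(x))
    if (length(ux) < 2L) return(list())
    lapply((ux[-length(ux)] + ux[-1L]) / 2,
           function(thr) list(kind = "numeric", threshold = thr))
  }
}

# exhaustive argmax of the (optionally gated) gain over all candidates of
# all variables, applying the same tie-break order (variable, then
# candidate order) by strict improvement
oracle_best_split <- function(X, P, alpha = 0.05, gate = FALSE) {
  L_parent <- oracle_loss(P, alpha)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    for (cand in oracle_candidates(X[[j]])) {
      left <- if (cand$kind == "numeric") {
        X[[j]] <= cand$threshold
      } else {
        as.character(X[[j]]) %in% cand$left_categories
      }
      if (!any(left) || all(left)) next
      g <- L_parent - oracle_loss(P[left, , drop = FALSE], alpha) -
        oracle_loss(P[!left, , drop = FALSE], alpha)
      g_eff <- g
      if (gate) {
        gt <- chi_square_gate(P[left, , drop = FALSE],
                              P[!left, , drop = FALSE], alpha)
        g_eff <- g * as.numeric(gt$gate)
      }
      if (is.null(best) || g_eff > best$g_eff) {
        best <- c(cand, list(g = g, g_eff = g_eff, variable = names(X)[j]))
      }
    }
  }
  if (is.null(best) || best$g_eff <= 0) return(NULL)
  best
}

# ---- brute-force infinitesimal jackknife ---------------------------------

oracle_ij <- function(preds, inbag, variance_floor = 1e-12) {
  B <- ncol(preds)
  n_train <- nrow(inbag)
  out <- numeric(nrow(preds))
  for (q in seq_len(nrow(preds))) {
    tbar <- mean(preds[q, ])
    raw <- 0
    for (i in seq_len(n_train)) {
      cov_i <- 0
      for (b in seq_len(B)) {
        cov_i <- cov_i + (inbag[i, b] - 1) * (preds[q, b] - tbar)
      }
      raw <- raw + (cov_i / B)^2
    }
    s2 <- mean((preds[q, ] - tbar)^2)
    out[q] <- max(raw - n_train / B * s2, variance_floor)
  }
  out
}

# ---- tiny hand-built trees for metric tests ------------------------------

manual_leaf <- function(id, depth, size, pi, alpha = 0.05) {
  treatments <- paste0("tau", seq_along(pi))
  sets <- potential_sets(pi, alpha)
  list(node_id = id, depth = depth,
       summary = list(size = size, pi = stats::setNames(pi, treatments),
                      useless = treatments[sets$useless],
                      potential = treatments[sets$potential],
                      pi_hat = stats::setNames(
                        truncated_probabilities(pi, sets$potential), treatments),
                      loss = 0),
       split = NULL, children = NULL)
}

manual_split_node <- function(id, depth, size, pi, variable, threshold,
                              left, right, gain = 1) {
  node <- manual_leaf(id, depth, size, pi)
  node$split <- list(variable = variable, var_index = 1L, kind = "numeric",
                     threshold = threshold, gain = gain, gain_eff = gain,
                     gate_p = 0.001)
  node$children <- list(left = left, right = right)
  node
}

manual_tree <- function(root, treatments, n) {
  structure(list(root = root, treatments = treatments,
                 settings = tree_settings(), n = n,
                 schema = c(x1 = "numeric", noise_1 = "numeric"),
                 gate_rejections = 0L),
            class = "psica_tree")
}
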