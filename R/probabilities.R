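# Estimation of pi_k(x): the probability that treatment k yields the best
# outcome for a participant with covariates x. Joint counterfactual outcome
# samples are drawn either from per-arm bootstrap ensembles ("bootstrap"
# method) or from normals with forest mean and infinitesimal-jackknife
# variance ("jackknife" method), and the best arm is counted per sample.

#' Settings for best-treatment probability estimation
#'
#' @param method `"jackknife"` (forest mean + IJ variance, normal sampling)
#'   or `"bootstrap"` (one model per bootstrap resample).
#' @param B number of joint outcome samples / ensemble members (default 500).
#' @param direction `"higher"` if larger outcomes are better (default), or
#'   `"lower"`.
#' @param seed master seed; sub-seeds for each arm and the sampling step are
#'   derived from it.
#' @return list of class `prob_settings`.
#' @export
prob_settings <- function(method = c("jackknife", "bootstrap"), B = 500L,
                          direction = c("higher", "lower"), seed = 1L) {
  structure(list(method = match.arg(method), B = as.integer(B),
                 direction = match.arg(direction), seed = seed),
            class = "prob_settings")
}

#' Draw joint counterfactual outcome samples
#'
#' For each of `B` samples, produces one hypothetical outcome per participant
#' and per treatment arm. Jackknife arms (`arm_forest`) contribute
#' independent normal draws with the arm's predicted mean and IJ variance at
#' each row; bootstrap arms (`bootstrap_ensemble`) contribute the b-th
#' member's prediction. Draws are independent across arms, matching the
#' assumed independence of error terms between treatment options.
#'
#' @param arms list with one fitted arm object per treatment, in treatment
#'   order.
#' @param X covariate table at which to sample (typically all participants).
#' @param settings a [prob_settings()] object.
#' @return numeric array of dimension `B x n x m`.
#' @export
draw_outcome_samples <- function(arms, X, settings = prob_settings()) {
  m <- length(arms)
  n <- nrow(X)
  B <- settings$B
  samples <- array(0, dim = c(B, n, m))
  for (k in seq_len(m)) {
    arm <- arms[[k]]
    if (inherits(arm, "bootstrap_ensemble")) {
      if (arm$B != B) {
        stop(sprintf("ensemble for arm %d has %d members but B = %d",
                     k, arm$B, B))
      }
      samples[, , k] <- t(predict_ensemble(arm, X))
    } else if (inherits(arm, "arm_forest")) {
      mu <- predict_mean(arm, X)
      # floor the per-row IJ variance at the arm's bagged-mean variance: the
      # IJ estimate is Monte-Carlo noisy at B ~ 100 trees and can undershoot
      # to ~0, which would make rows spuriously deterministic
      floor_k <- max(1e-12, arm$baseline_var)
      sdv <- sqrt(ij_variance(arm, X, variance_floor = floor_k))
      set.seed(derive_seed(settings$seed, stream = 11L, index = k))
      samples[, , k] <- matrix(stats::rnorm(B * n), B, n) *
        matrix(sdv, B, n, byrow = TRUE) + matrix(mu, B, n, byrow = TRUE)
    } else {
      stop("each arm must be an 'arm_forest' or 'bootstrap_ensemble'")
    }
  }
  samples
}

#' Estimate best-treatment probabilities from joint outcome samples
#'
#' For every participant, the fraction of joint samples in which each arm
#' attains the maximum outcome. Each sample contributes total mass `1/B`;
#' on an exact tie at the top the mass is split equally among the tied arms,
#' so every row of the result sums to 1.
#'
#' @param samples `B x n x m` array from [draw_outcome_samples()].
#' @param treatments optional treatment labels used as column names.
#' @return `n x m` matrix of probabilities (class `best_prob_table`).
#' @export
estimate_best_probabilities <- function(samples, treatments = NULL) {
  stopifnot(length(dim(samples)) == 3L)
  if (anyNA(samples)) stop("samples contain NA")
  B <- dim(samples)[1L]
  n <- dim(samples)[2L]
  m <- dim(samples)[3L]
  stopifnot(B >= 1L, m >= 2L)
  P <- matrix(0, n, m)
  for (b in seq_len(B)) {
    S <- matrix(samples[b, , ], n, m)
    mx <- S[, 1L]
    for (k in 2:m) mx <- pmax(mx, S[, k])
    wins <- S == mx
    P <- P + wins / rowSums(wins)
  }
  P <- P / B
  if (!is.null(treatments)) colnames(P) <- treatments
  class(P) <- c("best_prob_table", class(P))
  P
}

#' Estimate best-treatment probabilities for every trial participant
#'
#' Splits the trial into its treatment arms, fits the per-arm outcome
#' machinery, draws `B` joint counterfactual outcome samples at every
#' participant's covariates (in-arm and out-of-arm alike), and counts how
#' often each arm is best.
#'
#' @param trial a [validate_trial()] object.
#' @param forest_settings per-arm [forest_settings()]; a `NULL` `min_split`
#'   resolves per arm to one tenth of the arm size.
#' @param settings a [prob_settings()] object.
#' @return `n x m` `best_prob_table`, with the fitted `arms` attached as an
#'   attribute.
#' @export
fit_probabilities <- function(trial,
                              forest_settings = psicatree::forest_settings(),
                              settings = prob_settings()) {
  stopifnot(inherits(trial, "trial_data"))
  m <- length(trial$treatments)
  arms <- vector("list", m)
  names(arms) <- trial$treatments
  for (k in seq_len(m)) {
    idx <- which(as.integer(trial$t) == k)
    fs <- forest_settings
    if (is.null(fs$min_split)) {
      # resolution scales with the arm the forest actually sees: one tenth
      # of the arm size (the full-trial fraction would make leaf widths grow
      # with the number of arms and blur treatment-effect boundaries)
      fs$min_split <- max(2L * fs$min_bucket, ceiling(length(idx) / 10))
    }
    fs$seed <- derive_seed(settings$seed, stream = 3L, index = k)
    arms[[k]] <- if (settings$method == "bootstrap") {
      fit_bootstrap_ensemble(trial$X[idx, , drop = FALSE], trial$y[idx],
                             fs, B = settings$B, label = trial$treatments[k])
    } else {
      fit_arm_forest(trial$X[idx, , drop = FALSE], trial$y[idx],
                     fs, label = trial$treatments[k])
    }
  }
  samples <- draw_outcome_samples(arms, trial$X, settings)
  if (settings$direction == "lower") samples <- -samples
  P <- estimate_best_probabilities(samples, treatments = trial$treatments)
  attr(P, "arms") <- arms
  attr(P, "settings") <- settings
  P
}

#' Write a best-probability table to CSV
#'
#' Columns: `row` id plus one probability column per treatment.
#'
#' @param P a `best_prob_table` (or plain matrix).
#' @param path output file path.
#' @export
write_probabilities <- function(P, path) {
  df <- data.frame(row = seq_len(nrow(P)), unclass(P)[seq_len(nrow(P)), , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
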