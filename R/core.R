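#' psicatree: probabilistic subgroup identification trees
#'
#' Builds decision trees whose leaves report, for each subgroup of
#' randomized-trial participants, the probability that each treatment arm is
#' the best one and a label set of plausible best treatments. The pipeline is
#' [validate_trial()] -> [fit_probabilities()] -> [grow_tree()], wrapped by
#' [psica()]. Benchmark generators live in [make_model()] /
#' [simulate_trial()]; evaluation metrics in [accuracy_metric()],
#' [uncertainty_metric()], [suspect_metric()] and [decision_accuracy()].
#'
#' @keywords internal
"_PACKAGE"

# tolerance used everywhere a probability vector must sum to 1
.prob_tol <- 1e-9

#' Check and normalize a probability vector
#'
#' Inputs within `1e-9` of total mass 1 are renormalized; anything further
#' off is rejected.
#' @noRd
check_prob_vector <- function(pi, what = "pi") {
  if (!is.numeric(pi) || length(pi) < 1L || anyNA(pi)) {
    stop(sprintf("'%s' must be a numeric probability vector without NAs", what))
  }
  if (any(pi < -.prob_tol)) {
    stop(sprintf("'%s' has negative entries", what))
  }
  s <- sum(pi)
  if (abs(s - 1) > .prob_tol) {
    stop(sprintf("'%s' sums to %.12g, not 1 (tolerance 1e-9)", what, s))
  }
  pmax(pi, 0) / s
}

#' Validate a randomized-trial dataset
#'
#' Checks that a tabular trial dataset is usable: a real-valued outcome, a
#' treatment column whose labels all belong to the treatment set, no missing
#' outcomes or assignments, and every arm populated with at least
#' `min_arm_size` participants.
#'
#' @param data data frame with one row per participant.
#' @param outcome name of the numeric outcome column.
#' @param treatment name of the treatment-assignment column.
#' @param treatments character vector of treatment labels fixing the arm
#'   order used by all probability vectors. Defaults to the factor levels of
#'   the treatment column (or sorted unique values).
#' @param covariates names of covariate columns; defaults to every column
#'   except outcome and treatment.
#' @param categorical covariate names to force to factor even if their values
#'   parse as numbers.
#' @param min_arm_size minimum participants per arm (default 2).
#' @return An object of class `trial_data`: a list with elements `X`
#'   (covariate data frame), `y`, `t` (factor with levels = `treatments`),
#'   `treatments`, `n`, `p`.
#' @export
validate_trial <- function(data, outcome = "y", treatment = "t",
                           treatments = NULL, covariates = NULL,
                           categorical = NULL, min_arm_size = 2L) {
  stopifnot(is.data.frame(data))
  for (col in c(outcome, treatment)) {
    if (!col %in% names(data)) {
      stop(sprintf("column '%s' not found; available columns: %s",
                   col, paste(names(data), collapse = ", ")))
    }
  }
  y <- data[[outcome]]
  if (!is.numeric(y)) stop(sprintf("outcome column '%s' is not numeric", outcome))
  if (anyNA(y)) stop(sprintf("outcome column '%s' contains missing values", outcome))

  t_raw <- as.character(data[[treatment]])
  if (anyNA(t_raw)) stop(sprintf("treatment column '%s' contains missing values", treatment))
  if (is.null(treatments)) {
    treatments <- if (is.factor(data[[treatment]])) {
      levels(data[[treatment]])
    } else {
      sort(unique(t_raw))
    }
  }
  treatments <- as.character(treatments)
  if (anyDuplicated(treatments)) stop("treatment labels must be unique")
  if (length(treatments) < 2L) stop("at least two treatments are required")
  unknown <- setdiff(unique(t_raw), treatments)
  if (length(unknown)) {
    stop(sprintf("unknown treatment label(s) in '%s': %s",
                 treatment, paste(unknown, collapse = ", ")))
  }
  t <- factor(t_raw, levels = treatments)
  arm_sizes <- table(t)
  empty <- names(arm_sizes)[arm_sizes == 0L]
  if (length(empty)) {
    stop(sprintf("empty treatment arm(s): %s", paste(empty, collapse = ", ")))
  }
  small <- names(arm_sizes)[arm_sizes < min_arm_size]
  if (length(small)) {
    stop(sprintf("arm(s) smaller than min_arm_size = %d: %s",
                 min_arm_size, paste(small, collapse = ", ")))
  }

  if (is.null(covariates)) covariates <- setdiff(names(data), c(outcome, treatment))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop(sprintf("covariate column(s) not found: %s", paste(missing_cov, collapse = ", ")))
  }
  X <- data[, covariates, drop = FALSE]
  for (col in covariates) {
    if (col %in% categorical || is.character(X[[col]]) || is.logical(X[[col]])) {
      X[[col]] <- factor(X[[col]])
    }
    if (anyNA(X[[col]])) stop(sprintf("covariate '%s' contains missing values", col))
  }

  structure(
    list(X = X, y = as.numeric(y), t = t, treatments = treatments,
         n = nrow(X), p = ncol(X)),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: n = %d, p = %d covariates, %d arms\n",
              x$n, x$p, length(x$treatments)))
  print(table(x$t))
  invisible(x)
}

#' Split treatments into useless and potential sets
#'
#' Sorts the probabilities in increasing order and peels off the largest
#' prefix whose cumulative mass does not exceed `alpha`; those treatments are
#' "useless" (jointly improbable to be best at risk level `alpha`), the rest
#' are "potential". The potential set is never empty because the total mass 1
#' exceeds `alpha`. Ties are broken by treatment index (stable sort) so the
#' result is deterministic.
#'
#' @param pi probability vector (one entry per treatment, sums to 1).
#' @param alpha risk level in (0, 1).
#' @return list with integer index vectors `useless` and `potential` (sorted
#'   increasingly by treatment index).
#' @export
potential_sets <- function(pi, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  pi <- check_prob_vector(pi)
  m <- length(pi)
  ord <- order(pi, seq_len(m))      # stable: ties resolved by index
  cs <- cumsum(pi[ord])
  m_prime <- sum(cs <= alpha)       # largest prefix with cumulative mass <= alpha
  useless <- sort(ord[seq_len(m_prime)])
  list(useless = useless, potential = setdiff(seq_len(m), useless))
}

#' Truncated best-treatment probabilities
#'
#' Zeroes the probabilities outside the potential set and renormalizes the
#' remainder to sum to 1: the distribution a decision-maker would act on
#' after discarding useless treatments.
#'
#' @param pi probability vector.
#' @param potential integer indices of the potential treatment set.
#' @return numeric vector of the same length as `pi`.
#' @export
truncated_probabilities <- function(pi, potential) {
  pi <- check_prob_vector(pi)
  if (length(potential) < 1L) stop("potential set must be non-empty")
  mass <- sum(pi[potential])
  if (mass <= 0) stop("zero probability mass on the potential set")
  out <- numeric(length(pi))
  out[potential] <- pi[potential] / mass
  out
}

#' Zero-one misassignment cost matrix
#'
#' Cost `c[k, j]` of prescribing treatment `j` when treatment `k` is truly
#' best: 1 off the diagonal, 0 on it.
#'
#' @param m number of treatments.
#' @return `m x m` numeric matrix.
#' @export
zero_one_cost <- function(m) {
  stopifnot(m >= 2L)
  matrix(1, m, m) - diag(m)
}

#' @noRd
check_cost_matrix <- function(costs, m) {
  if (!is.matrix(costs) || nrow(costs) != m || ncol(costs) != m) {
    stop(sprintf("cost matrix must be %d x %d", m, m))
  }
  if (any(costs < 0)) stop("costs must be non-negative")
  if (any(diag(costs) != 0)) stop("cost matrix diagonal must be zero")
  costs
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter scheme: each consumer of randomness gets a distinct `stream`
#' number, and repeated draws within a stream an `index`; the derived seed is
#' `(seed * 20011 + stream * 1009 + index) mod (2^31 - 1)`, kept in 32-bit
#' integer range.
#' @noRd
derive_seed <- function(seed, stream, index = 0) {
  as.integer(((as.numeric(seed) %% 100000) * 20011 +
                as.numeric(stream) * 1009 + as.numeric(index)) %% 2147483647)
}
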