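# Benchmark trial generators M1-M6: known expected-outcome surfaces with
# randomized treatment assignment, appended irrelevant covariates and exact
# ground-truth best-treatment sets.

#' @noRd
rlaplace <- function(n, scale) {
  u <- stats::runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Construct a benchmark simulation model
#'
#' Six generative models for randomized trials with known best treatments:
#'
#' * **M1** (2 arms): smooth outcomes `2*tanh(2x) + 3` vs `2*tanh(x) + 2.3`,
#'   noise N(0, 0.8^2); arm 1 is best on the whole domain but the arms nearly
#'   coincide around x = -0.5.
#' * **M2 / M3** (2 arms): quadrant effects `0.5*I(x1>=0 & x2>=0)` for arm 1
#'   and `0.5*I(x1<0 & x2<0)` for arm 2; noise N(0, 0.2^2) for M2 and
#'   Laplace with scale 0.04 for M3 (the same "0.2 squared" second parameter
#'   read as the scale, paralleling the normal notation).
#' * **M4** (2 arms): main effect `sum(x1..x40)` plus effects
#'   `5*x1*I(x1>0.5)` (arm 1) and `5*I(x1<0.5 & x2>0.5)` (arm 2); noise
#'   N(0, 2^2); 160 extra irrelevant variables.
#' * **M5** (3 arms): lines `-0.7x - 0.7`, `-1.5x - 1.1`, `x - 1`; noise
#'   N(0, 0.2^2). `"M5_fig1"` is the shifted variant `-0.7x`, `-1.5x + 0.2`,
#'   `x - 1` whose arm crossings sit at x = 0.25 and x = 10/17.
#' * **M6** (4 arms): main effect `sum(x1..x40)` plus `5*x1*I(x1>0.5)` for
#'   arms 1 and 2 (an exact tie) and `10*I(x1<0 & x0=='K1')` for arm 3,
#'   where `x0` is a categorical variable with levels K1..K4; arm 4 never
#'   helps; noise N(0, 2^2); 160 extra irrelevant variables.
#'
#' All numeric covariates are U\[-1, 1\]; irrelevant pure-noise covariates
#' (`noise_1`, ...) are appended after the model's own columns: two for
#' M1/M2/M3/M5, 160 for M4/M6.
#'
#' @param name one of `"M1"` ... `"M6"`, or `"M5_fig1"`.
#' @param noise_sd optional override of the Gaussian noise standard
#'   deviation (used e.g. to study boundary recovery at low noise).
#' @return object of class `sim_model` with fields `name`, `m`,
#'   `treatments`, `f` (function: covariate data frame -> n x m expected
#'   outcomes), `rnoise`, `sample_covariates`, `predictive_vars`,
#'   `n_irrelevant`.
#' @export
make_model <- function(name = c("M1", "M2", "M3", "M4", "M5", "M6", "M5_fig1"),
                       noise_sd = NULL) {
  name <- match.arg(name)
  unif_cols <- function(n, cols) {
    as.data.frame(matrix(stats::runif(n * length(cols), -1, 1), n,
                         length(cols), dimnames = list(NULL, cols)))
  }
  gauss <- function(sd) function(n) stats::rnorm(n, 0, sd)

  model <- switch(
    name,
    M1 = list(
      m = 2L, signal_cols = "x1", n_irrelevant = 2L,
      predictive_vars = "x1", rnoise = gauss(0.8), noise_sd = 0.8,
      f = function(X) cbind(2 * tanh(2 * X$x1) + 3, 2 * tanh(X$x1) + 2.3)
    ),
    M2 = list(
      m = 2L, signal_cols = c("x1", "x2"), n_irrelevant = 2L,
      predictive_vars = c("x1", "x2"), rnoise = gauss(0.2), noise_sd = 0.2,
      f = function(X) cbind(0.5 * (X$x1 >= 0 & X$x2 >= 0),
                            0.5 * (X$x1 < 0 & X$x2 < 0))
    ),
    M3 = list(
      m = 2L, signal_cols = c("x1", "x2"), n_irrelevant = 2L,
      predictive_vars = c("x1", "x2"),
      rnoise = function(n) rlaplace(n, scale = 0.04), noise_sd = NA,
      f = function(X) cbind(0.5 * (X$x1 >= 0 & X$x2 >= 0),
                            0.5 * (X$x1 < 0 & X$x2 < 0))
    ),
    M4 = list(
      m = 2L, signal_cols = paste0("x", 1:40), n_irrelevant = 160L,
      predictive_vars = c("x1", "x2"), rnoise = gauss(2), noise_sd = 2,
      f = function(X) {
        main <- rowSums(as.matrix(X[, paste0("x", 1:40)]))
        cbind(main + 5 * X$x1 * (X$x1 > 0.5),
              main + 5 * (X$x1 < 0.5 & X$x2 > 0.5))
      }
    ),
    M5 = list(
      m = 3L, signal_cols = "x1", n_irrelevant = 2L,
      predictive_vars = "x1", rnoise = gauss(0.2), noise_sd = 0.2,
      f = function(X) cbind(-0.7 * X$x1 - 0.7, -1.5 * X$x1 - 1.1, X$x1 - 1)
    ),
    M5_fig1 = list(
      m = 3L, signal_cols = "x1", n_irrelevant = 2L,
      predictive_vars = "x1", rnoise = gauss(0.1), noise_sd = 0.1,
      f = function(X) cbind(-0.7 * X$x1, -1.5 * X$x1 + 0.2, X$x1 - 1)
    ),
    M6 = list(
      m = 4L, signal_cols = c("x0", paste0("x", 1:40)), n_irrelevant = 160L,
      predictive_vars = c("x0", "x1"), rnoise = gauss(2), noise_sd = 2,
      f = function(X) {
        main <- rowSums(as.matrix(X[, paste0("x", 1:40)]))
        boost12 <- 5 * X$x1 * (X$x1 > 0.5)
        boost3 <- 10 * (X$x1 < 0 & X$x0 == "K1")
        cbind(main + boost12, main + boost12, main + boost3, main)
      }
    )
  )
  if (!is.null(noise_sd)) {
    model$rnoise <- gauss(noise_sd)
    model$noise_sd <- noise_sd
  }
  model$name <- name
  model$treatments <- paste0("tau", seq_len(model$m))
  model$sample_covariates <- local({
    signal_cols <- model$signal_cols
    n_irr <- model$n_irrelevant
    has_cat <- name == "M6"
    function(n) {
      num_cols <- setdiff(signal_cols, "x0")
      X <- unif_cols(n, num_cols)
      if (has_cat) {
        X <- cbind(
          x0 = factor(sample(paste0("K", 1:4), n, replace = TRUE),
                      levels = paste0("K", 1:4)),
          X
        )
      }
      if (n_irr > 0L) X <- cbind(X, unif_cols(n, paste0("noise_", seq_len(n_irr))))
      X
    }
  })
  structure(model, class = "sim_model")
}

#' True best-treatment sets under a benchmark model
#'
#' The treatments whose expected outcome is within `tolerance` of the
#' row-wise maximum; with the default tolerance only exact ties (e.g. the
#' off-quadrant regions of M2/M3 or the arm-1/arm-2 tie of M6) produce
#' multi-treatment truth.
#'
#' @param model a [make_model()] object.
#' @param X covariate data frame (model schema).
#' @param tolerance tie tolerance (default 1e-9).
#' @return list of character vectors of treatment labels, one per row.
#' @export
true_best_set <- function(model, X, tolerance = 1e-9) {
  stopifnot(inherits(model, "sim_model"))
  F <- model$f(X)
  mx <- apply(F, 1L, max)
  lapply(seq_len(nrow(F)),
         function(i) model$treatments[F[i, ] >= mx[i] - tolerance])
}

#' Simulate a randomized trial from a benchmark model
#'
#' Covariates drawn from the model's domain, treatments assigned uniformly
#' at random independently of the covariates, outcomes equal to the expected
#' surface plus i.i.d. noise.
#'
#' @param model a [make_model()] object (or model name).
#' @param n number of participants.
#' @param seed RNG seed; fixes the whole draw.
#' @return object of class `simulated_trial`: list with `data` (data frame
#'   of covariates plus `y` and `t`), `trial` (a validated `trial_data`),
#'   `truth` (list of true best sets), `f_values`, `model`, `seed`.
#' @export
simulate_trial <- function(model, n, seed = 1L) {
  if (is.character(model)) model <- make_model(model)
  stopifnot(inherits(model, "sim_model"), n >= model$m)
  set.seed(seed)
  X <- model$sample_covariates(n)
  t <- factor(sample(model$treatments, n, replace = TRUE),
              levels = model$treatments)
  F <- model$f(X)
  y <- F[cbind(seq_len(n), as.integer(t))] + model$rnoise(n)
  data <- cbind(X, y = y, t = t)
  trial <- validate_trial(data, outcome = "y", treatment = "t",
                          treatments = model$treatments, min_arm_size = 1L)
  structure(
    list(data = data, trial = trial, truth = true_best_set(model, X),
         f_values = F, model = model, seed = seed),
    class = "simulated_trial"
  )
}
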