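# Serialization and pipeline commands: tree JSON round-trip, Graphviz DOT
# export, and the cmd_* functions behind the command-line script.

.tree_json_version <- "1"

#' @noRd
node_to_list <- function(node) {
  out <- list(node_id = node$node_id, depth = node$depth,
              summary = node$summary)
  if (!is.null(node$split)) {
    out$split <- node$split[!vapply(node$split, is.null, logical(1))]
    out$children <- list(left = node_to_list(node$children$left),
                         right = node_to_list(node$children$right))
  }
  out
}

#' @noRd
node_from_list <- function(lst) {
  node <- list(
    node_id = as.integer(lst$node_id), depth = as.integer(lst$depth),
    summary = list(
      size = as.integer(lst$summary$size),
      pi = unlist(lst$summary$pi),
      useless = as.character(unlist(lst$summary$useless)),
      potential = as.character(unlist(lst$summary$potential)),
      pi_hat = unlist(lst$summary$pi_hat),
      loss = as.numeric(lst$summary$loss)
    ),
    split = NULL, children = NULL
  )
  if (!is.null(lst$split)) {
    node$split <- lst$split
    node$split$kind <- as.character(lst$split$kind)
    node$split$variable <- as.character(lst$split$variable)
    if (node$split$kind == "numeric") {
      node$split$threshold <- as.numeric(lst$split$threshold)
    } else {
      node$split$left_categories <- as.character(unlist(lst$split$left_categories))
    }
    node$children <- list(left = node_from_list(lst$children$left),
                          right = node_from_list(lst$children$right))
  }
  node
}

#' Serialize a fitted tree to JSON
#'
#' Writes a versioned JSON document with the full node structure (split
#' rules, summaries, child links) at full double precision, so a re-loaded
#' tree predicts identically.
#'
#' @param tree a `psica_tree`.
#' @param path output file.
#' @export
write_tree_json <- function(tree, path) {
  doc <- list(
    format_version = .tree_json_version,
    treatments = tree$treatments,
    n = tree$n,
    schema = as.list(tree$schema),
    alpha = tree$settings$alpha,
    method = tree$settings$method,
    gate_rejections = tree$gate_rejections,
    root = node_to_list(tree$root)
  )
  # 17 significant digits: doubles survive the round trip bit for bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a tree from its JSON serialization
#'
#' @param path file written by [write_tree_json()].
#' @return a `psica_tree`.
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path)
  structure(
    list(root = node_from_list(doc$root),
         treatments = as.character(unlist(doc$treatments)),
         settings = tree_settings(alpha = as.numeric(doc$alpha),
                                  method = as.character(doc$method)),
         n = as.integer(doc$n),
         schema = vapply(doc$schema, as.character, character(1)),
         gate_rejections = as.integer(doc$gate_rejections)),
    class = "psica_tree"
  )
}

#' Export a tree to Graphviz DOT
#'
#' Leaves are rendered as boxes listing the potential treatments, the
#' aggregated probabilities to two decimals and the leaf size; internal
#' nodes show their split rule on the outgoing edges.
#'
#' @param tree a `psica_tree`.
#' @param path output `.dot` file.
#' @export
export_dot <- function(tree, path) {
  lines <- c("digraph psica_tree {", "  node [fontname=\"Helvetica\"];")
  emit <- function(node) {
    s <- node$summary
    if (is.null(node$children)) {
      probs <- paste(sprintf("%s: %.2f", tree$treatments, s$pi),
                     collapse = "\\n")
      lines <<- c(lines, sprintf(
        "  n%d [shape=box, label=\"{%s}\\n%s\\n|D| = %d\"];",
        node$node_id, paste(s$potential, collapse = ","), probs, s$size))
      return(invisible())
    }
    lines <<- c(lines, sprintf("  n%d [shape=ellipse, label=\"%s\\nn = %d\"];",
                               node$node_id, node$split$variable, s$size))
    lab_l <- if (node$split$kind == "numeric") {
      sprintf("<= %.4g", node$split$threshold)
    } else {
      paste("in", paste(node$split$left_categories, collapse = ","))
    }
    lab_r <- if (node$split$kind == "numeric") {
      sprintf("> %.4g", node$split$threshold)
    } else "otherwise"
    lines <<- c(lines,
                sprintf("  n%d -> n%d [label=\"%s\"];",
                        node$node_id, node$children$left$node_id, lab_l),
                sprintf("  n%d -> n%d [label=\"%s\"];",
                        node$node_id, node$children$right$node_id, lab_r))
    emit(node$children$left)
    emit(node$children$right)
  }
  emit(tree$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Fit a subgroup tree from a CSV file and write all artifacts
#'
#' Reads the trial table, validates it, estimates best-treatment
#' probabilities, grows the tree, and writes four artifacts into `out_dir`:
#' `probabilities.csv`, `tree.json`, `tree.dot` and `manifest.json` (the
#' full configuration, seeds and package version). Re-running with the same
#' configuration reproduces the artifacts byte for byte.
#'
#' @param input path to a CSV with header row.
#' @param outcome,treatment column names.
#' @param out_dir output directory (created if needed).
#' @param categorical covariate names to force categorical.
#' @param method probability method (`"jackknife"` or `"bootstrap"`).
#' @param mtry `"all"` or `"sqrt"`.
#' @param B joint samples; `n_trees` trees per forest.
#' @param n_trees trees per forest.
#' @param alpha risk level.
#' @param direction `"higher"` or `"lower"` outcomes are better.
#' @param tree_method `"preprune"` or `"grow"`.
#' @param min_node_tree,min_node_forest minimum node sizes (`NULL` =
#'   `ceiling(n/5)` and `ceiling(n/10)`).
#' @param max_depth optional tree depth cap.
#' @param costs_path optional CSV with an m x m cost matrix.
#' @param seed master seed.
#' @param verbose log arm sizes and phase timings.
#' @return invisibly, a list with the tree, probabilities and artifact
#'   paths.
#' @export
cmd_fit <- function(input, outcome = "y", treatment = "t", out_dir = ".",
                    categorical = NULL, method = "jackknife", mtry = "all",
                    B = 500L, n_trees = 100L, alpha = 0.05,
                    direction = "higher", tree_method = "preprune",
                    min_node_tree = NULL, min_node_forest = NULL,
                    max_depth = Inf, costs_path = NULL, seed = 1L,
                    verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  data <- utils::read.csv(input, stringsAsFactors = FALSE)
  trial <- validate_trial(data, outcome = outcome, treatment = treatment,
                          categorical = categorical)
  if (verbose) {
    message(sprintf("arms: %s",
                    paste(sprintf("%s=%d", trial$treatments, table(trial$t)),
                          collapse = ", ")))
  }
  costs <- NULL
  if (!is.null(costs_path)) {
    costs <- as.matrix(utils::read.csv(costs_path, header = FALSE))
    dimnames(costs) <- NULL
    costs <- check_cost_matrix(costs, length(trial$treatments))
  }
  fs <- forest_settings(n_trees = n_trees, mtry = mtry,
                        min_split = min_node_forest)
  ps <- prob_settings(method = method, B = B, direction = direction,
                      seed = seed)
  P <- fit_probabilities(trial, fs, ps)
  t1 <- proc.time()[["elapsed"]]
  tree <- grow_tree(trial, P,
                    tree_settings(alpha = alpha, min_node = min_node_tree,
                                  max_depth = max_depth, method = tree_method,
                                  costs = costs))
  t2 <- proc.time()[["elapsed"]]
  if (verbose) {
    message(sprintf("probabilities %.1fs, tree %.1fs, gate rejections: %d",
                    t1 - t0, t2 - t1, tree$gate_rejections))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(probabilities = file.path(out_dir, "probabilities.csv"),
                tree_json = file.path(out_dir, "tree.json"),
                tree_dot = file.path(out_dir, "tree.dot"),
                manifest = file.path(out_dir, "manifest.json"))
  write_probabilities(P, paths$probabilities)
  write_tree_json(tree, paths$tree_json)
  export_dot(tree, paths$tree_dot)
  manifest <- list(
    package = "psicatree",
    version = as.character(utils::packageVersion("psicatree")),
    input = input, outcome = outcome, treatment = treatment,
    method = method, mtry = mtry, B = B, n_trees = n_trees, alpha = alpha,
    direction = direction, tree_method = tree_method, seed = seed,
    n = trial$n, p = trial$p, treatments = trial$treatments,
    gate_rejections = tree$gate_rejections
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(tree = tree, probabilities = P, paths = paths))
}

#' Simulate a benchmark trial to CSV plus a ground-truth sidecar
#'
#' Writes the trial table as CSV and a JSON sidecar with the true best sets,
#' treatment labels and predictive variables.
#'
#' @param model benchmark model name.
#' @param n sample size.
#' @param seed RNG seed.
#' @param out path of the output CSV; the sidecar gets extension
#'   `.truth.json`.
#' @return invisibly, the `simulated_trial`.
#' @export
cmd_simulate <- function(model, n, seed = 1L, out = "trial.csv") {
  sim <- simulate_trial(make_model(model), n, seed = seed)
  utils::write.csv(sim$data, out, row.names = FALSE)
  truth_path <- sub("\\.csv$", "", out)
  truth_path <- paste0(truth_path, ".truth.json")
  jsonlite::write_json(
    list(model = model, n = n, seed = seed,
         treatments = sim$model$treatments,
         predictive_vars = sim$model$predictive_vars,
         true_best = sim$truth),
    truth_path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(sim)
}

#' Evaluate a serialized tree against a ground-truth sidecar
#'
#' @param tree_json tree file from [write_tree_json()].
#' @param data_csv trial CSV (covariates used for routing).
#' @param truth_json sidecar from [cmd_simulate()].
#' @param out optional CSV path for the one-row metric report.
#' @return one-row data frame with accuracy, uncertainty, suspect (NA for a
#'   root-only tree) and decision accuracy.
#' @export
cmd_evaluate <- function(tree_json, data_csv, truth_json, out = NULL) {
  tree <- read_tree_json(tree_json)
  data <- utils::read.csv(data_csv, stringsAsFactors = FALSE)
  truth_doc <- jsonlite::read_json(truth_json)
  truth <- lapply(truth_doc$true_best, function(x) as.character(unlist(x)))
  if (length(truth) != nrow(data)) stop("truth/data row mismatch")
  for (col in names(tree$schema)) {
    if (tree$schema[[col]] == "factor") data[[col]] <- factor(data[[col]])
  }
  pred <- predict_sets(tree, data[, names(tree$schema), drop = FALSE])
  report <- data.frame(
    model = as.character(truth_doc$model), n = nrow(data),
    accuracy = accuracy_metric(pred$potential, truth),
    uncertainty = uncertainty_metric(pred$potential, truth),
    suspect = suspect_metric(
      tree, as.character(unlist(truth_doc$predictive_vars))),
    decision_accuracy = decision_accuracy(pred$pi_hat, truth),
    stringsAsFactors = FALSE
  )
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  report
}

#' Run a benchmark grid cell end-to-end and write the results CSV
#'
#' @param model,n,method one grid cell.
#' @param reps replicates.
#' @param seed master seed.
#' @param B,n_trees,alpha estimation settings.
#' @param out results CSV path.
#' @return invisibly, the per-replicate results data frame.
#' @export
cmd_benchmark <- function(model, n, method = "m1", reps = 5L, seed = 1L,
                          B = 500L, n_trees = 100L, alpha = 0.05,
                          out = "results.csv") {
  grid <- experiment_grid(models = model, ns = n, methods = method,
                          reps = reps, alpha = alpha, B = B,
                          n_trees = n_trees, seed = seed)
  results <- run_experiment(grid)
  utils::write.csv(results, out, row.names = FALSE)
  invisible(results)
}
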