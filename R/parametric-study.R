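# Parametric simulation engine: map a two-class multivariate-normal
# scenario to the MSE decomposition of the split-sample design and an
# optimal-split recommendation, using the compound covariate predictor.

#' Configure a parametric split-optimization study
#'
#' @param scenario A [simulation_scenario()].
#' @param grid Training sizes to evaluate; default `seq(10, n - 10, 10)`.
#' @param R Number of random training subsets drawn per grid point.
#' @param seed Master seed; every random component of [run_scenario()] is
#'   derived deterministically from it.
#' @param alpha_grid Candidate gene-selection cutoffs passed to
#'   [optimal_alpha()].
#' @param alpha_mc Monte Carlo draws per candidate cutoff.
#' @param n_full_reps Independent replicate datasets of size `n` used to
#'   estimate the full-data classifier's mean true accuracy (the bias
#'   reference).
#' @param plateau_tol Plateau tolerance forwarded to [summarize_mse()].
#' @param dataset Optional pre-simulated `"expression_dataset"` to use as
#'   the study dataset instead of drawing a fresh one (it must match the
#'   scenario's dimensions); useful for comparing the parametric and
#'   nonparametric engines on one shared dataset.
#' @param full_data_reference How the bias reference (the mean true
#'   accuracy at training size `n`) is computed: `"replicates"` (default)
#'   averages the theoretical accuracies of full-data classifiers over
#'   `n_full_reps` independent replicate datasets, which stabilizes
#'   scenario-level summaries; `"dataset"` uses the theoretical accuracy of
#'   the classifier developed on the study dataset itself, conditioning the
#'   whole decomposition on that dataset (the natural comparator for the
#'   nonparametric algorithm, which only ever sees one dataset).
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(scenario, grid = NULL, R = 200, seed = 1,
                         alpha_grid = c(1e-6, 1e-5, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1),
                         alpha_mc = 50, n_full_reps = 50, plateau_tol = 0.001,
                         dataset = NULL,
                         full_data_reference = c("replicates", "dataset")) {
  full_data_reference <- match.arg(full_data_reference)
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "expression_dataset"))
    if (!identical(dim(dataset$expr), c(scenario$p, scenario$n))) {
      stop("'dataset' dimensions do not match the scenario")
    }
  }
  n <- scenario$n
  if (is.null(grid)) grid <- seq(10L, n - 10L, by = 10L)
  grid <- as.integer(grid)
  if (length(grid) == 0L || any(grid < 10L) || any(grid > n - 10L)) {
    stop("'grid' must lie within [10, n - 10]")
  }
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (R < 2) stop("'R' must be at least 2")
  structure(
    list(scenario = scenario, grid = grid, R = as.integer(R),
         seed = as.integer(seed), alpha_grid = alpha_grid,
         alpha_mc = as.integer(alpha_mc),
         n_full_reps = as.integer(n_full_reps), plateau_tol = plateau_tol,
         dataset = dataset, full_data_reference = full_data_reference),
    class = "study_config"
  )
}

# Stratified training-subset indices: class counts proportional to the
# dataset's class proportions, rounded, with at least 2 per class.
.stratified_train_idx <- function(labels, t) {
  lv <- levels(labels)
  i1 <- which(labels == lv[1])
  i2 <- which(labels == lv[2])
  t1 <- round(t * length(i1) / length(labels))
  t1 <- min(max(t1, 2L), t - 2L)
  if (t1 < 2L || t - t1 < 2L) stop("training size too small for a stratified split")
  if (t1 > length(i1) || t - t1 > length(i2)) {
    stop("training size exceeds available samples in a class")
  }
  c(sample(i1, t1), sample(i2, t - t1))
}

#' Mean true accuracy of the full-dataset classifier under a scenario
#'
#' Simulates `n_reps` independent datasets of the scenario's full size `n`,
#' fits the compound covariate predictor on each at the supplied (or
#' optimized) significance cutoff, and averages the exact model-based
#' accuracies.  This is the reference quantity the split-sample design is
#' trying to estimate: the accuracy of the classifier developed on all `n`
#' cases.
#'
#' @param scenario A [simulation_scenario()].
#' @param n_reps Number of replicate datasets.
#' @param alpha Gene-selection cutoff; `NULL` (default) optimizes it for
#'   training size `n` via [optimal_alpha()].
#' @param alpha_grid,alpha_mc Passed to [optimal_alpha()] when `alpha` is
#'   `NULL`.
#' @param seed Optional seed.
#' @return List with `mean_accuracy`, `accuracies` (length `n_reps`),
#'   `alpha` and `se` (Monte Carlo standard error of the mean).
#' @export
mean_full_data_accuracy <- function(scenario, n_reps = 100, alpha = NULL,
                                    alpha_grid = c(1e-6, 1e-5, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1),
                                    alpha_mc = 50, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alpha)) {
    alpha <- as.numeric(optimal_alpha(scenario$n, scenario,
                                      alpha_grid = alpha_grid, n_mc = alpha_mc))
  }
  accs <- vapply(seq_len(n_reps), function(r) {
    d <- simulate_dataset(scenario)
    true_accuracy(fit_ccp(d, alpha = alpha), scenario)
  }, numeric(1))
  list(mean_accuracy = mean(accs), accuracies = accs, alpha = alpha,
       se = stats::sd(accs) / sqrt(n_reps))
}

#' Run a parametric split-optimization study
#'
#' Implements the model-based pipeline: simulate a dataset from the
#' scenario; for each training size `t` on the grid, optimize the
#' gene-selection cutoff for that size, draw `R` stratified training
#' subsets, fit a compound covariate predictor on each, record its exact
#' true accuracy (giving the accuracy-variance term `A` and the mean
#' accuracy at `t`) and its hold-out accuracy on the complementary `n - t`
#' cases; compute the binomial-variance term `V` from the mean accuracy,
#' and the squared-bias term `B` against the mean true accuracy of
#' full-data classifiers estimated from `n_full_reps` independent replicate
#' datasets.  Deterministic given the config's seed.
#'
#' @param config A [study_config()].
#' @return Object of class `"scenario_result"`: list with `decomposition`
#'   ([mse_decomposition()]), `recommendation` ([summarize_mse()]),
#'   `mean_true_accuracy` and `mean_holdout_accuracy` per grid point,
#'   `full_data_accuracy`, `alpha_by_t`, `alpha_full` and `config`.
#' @examples
#' \donttest{
#' sc <- simulation_scenario(n = 60, p = 300, m = 10, effect = 1.5)
#' res <- run_scenario(study_config(sc, R = 50, seed = 7))
#' res$recommendation
#' }
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "study_config"))
  scenario <- config$scenario
  grid <- config$grid
  n <- scenario$n
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(grid) + 3L)

  alpha_by_t <- vapply(seq_along(grid), function(i) {
    as.numeric(optimal_alpha(grid[i], scenario,
                             alpha_grid = config$alpha_grid,
                             n_mc = config$alpha_mc, seed = seeds[i]))
  }, numeric(1))

  S <- if (is.null(config$dataset)) {
    simulate_dataset(scenario, seed = seeds[length(grid) + 1L])
  } else {
    config$dataset
  }
  lv <- levels(S$labels)

  set.seed(seeds[length(grid) + 2L])
  A <- V <- mean_true <- mean_holdout <- numeric(length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    acc_true <- acc_hold <- numeric(config$R)
    for (r in seq_len(config$R)) {
      tr <- .stratified_train_idx(S$labels, t)
      te <- setdiff(seq_len(n), tr)
      idx1 <- tr[S$labels[tr] == lv[1]]
      idx2 <- tr[S$labels[tr] == lv[2]]
      tt <- .pooled_t_core(S$expr, idx1, idx2)
      mod <- .ccp_from_stats(tt, S$expr, idx1, idx2, alpha_by_t[i], lv, t - 2L)
      acc_true[r] <- true_accuracy(mod, scenario)
      pred <- predict(mod, S$expr[, te, drop = FALSE])
      acc_hold[r] <- mean(pred == S$labels[te])
    }
    A[i] <- accuracy_variance(acc_true)
    mean_true[i] <- mean(acc_true)
    mean_holdout[i] <- mean(acc_hold)
    V[i] <- binomial_variance(mean_true[i], n - t)
  }

  if (identical(config$full_data_reference, "dataset")) {
    set.seed(seeds[length(grid) + 3L])
    alpha_n <- as.numeric(optimal_alpha(n, scenario,
                                        alpha_grid = config$alpha_grid,
                                        n_mc = config$alpha_mc))
    full <- list(mean_accuracy = true_accuracy(fit_ccp(S, alpha = alpha_n), scenario),
                 alpha = alpha_n)
  } else {
    full <- mean_full_data_accuracy(scenario, n_reps = config$n_full_reps,
                                    alpha_grid = config$alpha_grid,
                                    alpha_mc = config$alpha_mc,
                                    seed = seeds[length(grid) + 3L])
  }
  B <- (mean_true - full$mean_accuracy)^2

  decomp <- mse_decomposition(n, grid, A, V, B)
  rec <- summarize_mse(decomp, plateau_tol = config$plateau_tol,
                       full_data_accuracy = full$mean_accuracy)
  structure(
    list(decomposition = decomp, recommendation = rec,
         mean_true_accuracy = mean_true, mean_holdout_accuracy = mean_holdout,
         full_data_accuracy = full$mean_accuracy,
         alpha_by_t = alpha_by_t, alpha_full = full$alpha, config = config),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- x$config$scenario
  cat(sprintf("Parametric study: n = %d, p = %d, m = %d, effect = %.2f\n",
              sc$n, sc$p, sc$m, sc$effect))
  print(x$recommendation)
  invisible(x)
}

# Table-style cell: optimal t, "+" when the plateau reaches the grid
# maximum, and the full-data accuracy as a percentage (">99%" above 99.5).
.format_cell <- function(rec) {
  acc <- rec$full_data_accuracy
  pct <- if (acc > 0.995) ">99%" else sprintf("%d%%", round(100 * acc))
  sprintf("%d%s(%s)", if (rec$plateau_to_max) min(rec$plateau) else rec$t_opt,
          if (rec$plateau_to_max) "+" else "", pct)
}

#' Summarize a batch of scenarios as an allocation table
#'
#' Runs [run_scenario()] for each configuration and assembles one summary
#' row per scenario: the optimal training size, whether the RMSE plateau
#' extends to the largest evaluated size (flagged with `+`), the full-data
#' accuracy, and a compact formatted cell such as `"70+(>99%)"`.
#'
#' @param configs List of [study_config()] objects.
#' @return Data frame with columns `n`, `p`, `m`, `effect`, `prevalence`,
#'   `t_opt`, `plateau_from`, `plateau_to_max`, `accuracy`, `cell`, plus the
#'   full results in the `"results"` attribute.
#' @export
scenario_grid <- function(configs) {
  if (length(configs) == 0L) stop("'configs' must be a non-empty list")
  results <- lapply(configs, run_scenario)
  rows <- lapply(results, function(res) {
    sc <- res$config$scenario
    rec <- res$recommendation
    data.frame(
      n = sc$n, p = sc$p, m = sc$m, effect = sc$effect,
      prevalence = sc$prevalence,
      t_opt = rec$t_opt, plateau_from = min(rec$plateau),
      plateau_to_max = rec$plateau_to_max,
      accuracy = rec$full_data_accuracy, cell = .format_cell(rec),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
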