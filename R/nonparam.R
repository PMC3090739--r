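# Nonparametric (resampling) split recommendation for a specific dataset
# and plug-in classifier: a learning curve of mean error over repeated
# random splits supplies the squared-bias term; a split-then-bootstrap
# scheme supplies the variance (A + V composite); their sum is the MSE.

#' Plug-in classifier contract: the compound covariate predictor
#'
#' The nonparametric algorithm accepts any classifier expressed as a list
#' with elements `fit(expr, labels) -> model` and
#' `predict(model, expr) -> labels`; this constructor provides the
#' package's reference implementation.  With `alpha = NULL` (the default)
#' the gene-selection cutoff is tuned adaptively per training-set *size*:
#' inside [learning_curve()], [variance_curve()] and [recommend_split()]
#' the cutoff for each grid size is chosen up front by cross-validation
#' ([optimal_alpha()] in data mode, averaged over three stratified subsets
#' of that size) and cached; when the classifier is used standalone, the
#' first training set of a given size triggers the tuning.  Small training
#' sets genuinely need more permissive cutoffs than large ones, so a
#' single fixed cutoff would cripple one end of the learning curve.
#'
#' @param alpha Gene-selection cutoff in (0, 1], or `NULL` to tune by
#'   cross-validation per training-set size.
#' @param alpha_grid Candidate cutoffs used when tuning.
#' @return Object of class `"split_classifier"`.
#' @export
ccp_classifier <- function(alpha = NULL,
                           alpha_grid = c(1e-6, 1e-5, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1)) {
  if (is.null(alpha)) {
    cache <- new.env(parent = emptyenv())
    fit_fun <- function(expr, labels) {
      key <- as.character(ncol(expr))
      a <- cache[[key]]
      if (is.null(a)) {
        a <- as.numeric(optimal_alpha(ncol(expr),
                                      expression_dataset(expr, labels),
                                      alpha_grid = alpha_grid))
        cache[[key]] <- a
      }
      fit_ccp(expr, labels, alpha = a)
    }
  } else {
    fit_fun <- function(expr, labels) fit_ccp(expr, labels, alpha = alpha)
  }
  structure(
    list(
      name = "ccp",
      alpha = alpha,
      fit = fit_fun,
      predict = function(model, expr) predict(model, expr)
    ),
    class = "split_classifier"
  )
}

#' Wrap fit/predict functions as a plug-in classifier
#'
#' @param fit Function `(expr, labels) -> model`.
#' @param predict Function `(model, expr) -> predicted labels`.
#' @param name Display name.
#' @return Object of class `"split_classifier"`.
#' @export
split_classifier <- function(fit, predict, name = "custom") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(name = name, alpha = NA, fit = fit, predict = predict),
            class = "split_classifier")
}

# For the adaptive CCP, pre-tune the selection cutoff for every training
# size on the grid before resampling begins: per size, average the
# cross-validated accuracy profile over a few stratified subsets (one
# subset is a noisy basis for the choice) and cache the winner.  The same
# resolved classifier is shared by the learning and variance curves.
.resolve_classifier <- function(classifier, dataset, grid = NULL) {
  stopifnot(inherits(classifier, "split_classifier"))
  if (!identical(classifier$name, "ccp") || !is.null(classifier$alpha) ||
      is.null(grid) || isTRUE(attr(classifier, "tuned"))) {
    return(classifier)
  }
  alpha_grid <- sort(environment(classifier$fit)$alpha_grid)
  cache <- environment(classifier$fit)$cache
  n_tune <- 3L
  for (t in grid) {
    key <- as.character(t)
    if (!is.null(cache[[key]])) next
    acc <- rep(0, length(alpha_grid))
    for (r in seq_len(n_tune)) {
      idx <- .stratified_train_idx(dataset$labels, t)
      sub <- expression_dataset(dataset$expr[, idx, drop = FALSE],
                                dataset$labels[idx])
      acc <- acc + .optimal_alpha_cv(sub, alpha_grid, folds = 5)
    }
    cache[[key]] <- alpha_grid[which.max(acc)]
  }
  attr(classifier, "tuned") <- TRUE
  classifier
}

.default_grid <- function(n) {
  if (n < 30) stop("need at least 30 samples to evaluate a split grid")
  seq(10L, n - 10L, by = 10L)
}

#' Learning curve of classification error over random splits
#'
#' For each training size `t` on the grid, the dataset is split
#' `n_splits` times into a stratified training set of size `t` and the
#' complementary test set; the classifier is trained on each training part
#' and its error measured on the test part.  The per-`t` mean error `w` is
#' then smoothed by [fit_error_curve()] (weighted spline with case weights
#' `1/t`, isotonic fallback), which also extrapolates the fitted error to
#' `t = n`.
#'
#' @param dataset An `"expression_dataset"` with at least 30 samples.
#' @param classifier A `"split_classifier"`; default [ccp_classifier()].
#' @param grid Training sizes; default `seq(10, n - 10, 10)`.
#' @param n_splits Random splits per grid point.
#' @param seed Optional seed.
#' @param smoothing_df Forwarded to [fit_error_curve()].
#' @return Object of class `"learning_curve"`: `grid`, `mean_error`,
#'   `n_splits`, `fit` (a `"curve_fit"`), `n`.
#' @export
learning_curve <- function(dataset, classifier = ccp_classifier(), grid = NULL,
                           n_splits = 1000, seed = NULL, smoothing_df = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- ncol(dataset$expr)
  if (is.null(grid)) grid <- .default_grid(n)
  grid <- as.integer(grid)
  if (min(grid) < 10L || max(grid) > n - 10L) stop("'grid' must lie within [10, n - 10]")
  if (n_splits < 2) stop("'n_splits' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  classifier <- .resolve_classifier(classifier, dataset, grid)
  w <- numeric(length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    err <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      tr <- .stratified_train_idx(dataset$labels, t)
      te <- setdiff(seq_len(n), tr)
      err[s] <- tryCatch({
        mod <- classifier$fit(dataset$expr[, tr, drop = FALSE], dataset$labels[tr])
        pred <- classifier$predict(mod, dataset$expr[, te, drop = FALSE])
        mean(pred != dataset$labels[te])
      }, error = function(e) {
        stop(sprintf("classifier failed at t = %d, split %d: %s",
                     t, s, conditionMessage(e)), call. = FALSE)
      })
    }
    w[i] <- mean(err)
  }
  fit <- fit_error_curve(grid, w, n, smoothing_df = smoothing_df)
  structure(
    list(grid = grid, mean_error = w, n_splits = as.integer(n_splits),
         fit = fit, n = n, classifier = classifier$name),
    class = "learning_curve"
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf(
    "Learning curve (%s, %d splits/point): mean error %.3f at t = %d down to %.3f at t = %d\n",
    x$classifier, x$n_splits, x$mean_error[1], x$grid[1],
    x$mean_error[length(x$grid)], x$grid[length(x$grid)]
  ))
  print(x$fit)
  invisible(x)
}

#' Squared-bias curve from a fitted learning curve
#'
#' `B(t) = (what(t) - what(n))^2` where `what` is the fitted (smoothed)
#' error curve; only fitted values are used, so `B(n) = 0` by construction.
#'
#' @param curve A [learning_curve()].
#' @return Numeric vector of squared biases, one per grid point.
#' @export
bias2_curve <- function(curve) {
  stopifnot(inherits(curve, "learning_curve"))
  f_t <- predict(curve$fit, curve$grid)
  f_n <- predict(curve$fit, curve$n)
  (f_t - f_n)^2
}

#' Bootstrap variance of split-sample accuracy (A + V composite)
#'
#' For each training size `t` and each of `n_boot` replicates: draw a fresh
#' stratified split into a training part (size `t`) and test part (size
#' `n - t`); resample with replacement within the training part and within
#' the test part (splitting before resampling keeps the two parts
#' disjoint); train the classifier on the resampled training part and
#' measure its accuracy on the resampled test part.  The sample variance of
#' the replicate accuracies estimates the combined accuracy-variance plus
#' binomial-variance contribution (`A + V`); the two are never separated.
#' A training resample that loses a class (or otherwise breaks the
#' classifier) is redrawn, up to `max_retry` times.
#'
#' @param dataset An `"expression_dataset"`.
#' @param classifier A `"split_classifier"`.
#' @param grid Training sizes; default `seq(10, n - 10, 10)`.
#' @param n_boot Bootstrap replicates per grid point (>= 2).
#' @param seed Optional seed.
#' @param max_retry Redraw budget per replicate for degenerate resamples.
#' @return Object of class `"variance_curve"`: `grid`, `av_estimate`,
#'   `n_boot`, `n`.
#' @export
variance_curve <- function(dataset, classifier = ccp_classifier(), grid = NULL,
                           n_boot = 1000, seed = NULL, max_retry = 20) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- ncol(dataset$expr)
  if (is.null(grid)) grid <- .default_grid(n)
  grid <- as.integer(grid)
  if (n_boot < 2) stop("'n_boot' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  classifier <- .resolve_classifier(classifier, dataset, grid)
  av <- numeric(length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    acc <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      tr <- .stratified_train_idx(dataset$labels, t)
      te <- setdiff(seq_len(n), tr)
      done <- FALSE
      for (attempt in seq_len(max_retry)) {
        tr_b <- sample(tr, t, replace = TRUE)
        te_b <- sample(te, n - t, replace = TRUE)
        lab_tr <- droplevels(dataset$labels[tr_b])
        if (nlevels(lab_tr) < 2L || min(table(lab_tr)) < 2L) next
        ok <- tryCatch({
          mod <- classifier$fit(dataset$expr[, tr_b, drop = FALSE], dataset$labels[tr_b])
          pred <- classifier$predict(mod, dataset$expr[, te_b, drop = FALSE])
          acc[b] <- mean(pred == dataset$labels[te_b])
          TRUE
        }, error = function(e) FALSE)
        if (ok) { done <- TRUE; break }
      }
      if (!done) {
        stop(sprintf("degenerate bootstrap resamples at t = %d after %d retries",
                     t, max_retry))
      }
    }
    av[i] <- stats::var(acc)
  }
  structure(
    list(grid = grid, av_estimate = av, n_boot = as.integer(n_boot), n = n),
    class = "variance_curve"
  )
}

#' Recommend the optimal training/test split for a dataset
#'
#' The data-driven algorithm: estimate the squared-bias curve from a
#' smoothed learning curve over `n_splits` random splits per training size
#' ([learning_curve()], [bias2_curve()]) and the variance curve from
#' `n_boot` split-then-bootstrap replicates ([variance_curve()]); assemble
#' `mse(t)` as their sum and report the RMSE-minimizing training size, the
#' plateau of practically equivalent sizes, and the excess errors of the
#' 1/2 and 2/3 rules of thumb.  The full-data accuracy is reported as one
#' minus the fitted error extrapolated to `t = n`.
#'
#' At least 1,000 splits and 1,000 bootstrap replicates are recommended for
#' adequately de-noised MSE curves; smaller values are accepted (with a
#' message) for exploratory runs.
#'
#' @param dataset An `"expression_dataset"` (n >= 30).
#' @param classifier A `"split_classifier"`; default [ccp_classifier()].
#' @param grid Training sizes; default `seq(10, n - 10, 10)`.
#' @param n_splits Random splits per grid point for the learning curve.
#' @param n_boot Bootstrap replicates per grid point for the variance
#'   curve.
#' @param plateau_tol Plateau tolerance in RMSE units.
#' @param seed Master seed for the whole procedure.
#' @param smoothing_df Forwarded to [fit_error_curve()].
#' @return Object of class `"split_analysis"`: `decomposition` (with the
#'   bootstrap `A + V` composite in the `A` slot and
#'   `variance_components = "composite"`), `recommendation`,
#'   `learning_curve`, `variance_curve`, `classifier`.
#' @examples
#' \donttest{
#' sc <- simulation_scenario(n = 60, p = 200, m = 20, effect = 1.5)
#' d <- simulate_dataset(sc, seed = 3)
#' recommend_split(d, n_splits = 50, n_boot = 50, seed = 9)
#' }
#' @export
recommend_split <- function(dataset, classifier = ccp_classifier(), grid = NULL,
                            n_splits = 1000, n_boot = 1000,
                            plateau_tol = 0.001, seed = NULL,
                            smoothing_df = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- ncol(dataset$expr)
  if (is.null(grid)) grid <- .default_grid(n)
  if (n_splits < 1000 || n_boot < 1000) {
    message("fewer than the recommended 1,000 splits/bootstrap replicates; ",
            "MSE curves may be under-smoothed")
  }
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  classifier <- .resolve_classifier(classifier, dataset, grid)
  lc <- learning_curve(dataset, classifier, grid = grid, n_splits = n_splits,
                       seed = seeds[1], smoothing_df = smoothing_df)
  B <- bias2_curve(lc)
  vc <- variance_curve(dataset, classifier, grid = grid, n_boot = n_boot,
                       seed = seeds[2])
  decomp <- mse_decomposition(n, grid, A = vc$av_estimate,
                              V = rep(0, length(grid)), B = B,
                              variance_components = "composite")
  rec <- summarize_mse(decomp, plateau_tol = plateau_tol,
                       full_data_accuracy = 1 - predict(lc$fit, n))
  structure(
    list(decomposition = decomp, recommendation = rec,
         learning_curve = lc, variance_curve = vc,
         classifier = classifier$name),
    class = "split_analysis"
  )
}

#' @export
print.split_analysis <- function(x, ...) {
  cat(sprintf("Nonparametric split analysis (%s classifier, %d splits, %d bootstraps)\n",
              x$classifier, x$learning_curve$n_splits, x$variance_curve$n_boot))
  print(x$recommendation)
  invisible(x)
}
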