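# MSE decomposition of the split-sample accuracy estimate:
#   MSE(t) = A(t) + V(t) + B(t)
# A: variance of the true accuracy across training sets of size t;
# V: binomial variance of the test-set estimate, acc(1-acc)/(n-t);
# B: squared bias of mean accuracy at t relative to training on all n.
# The decomposition is used up to a constant of proportionality; the
# constant is fixed at 1 since only comparisons across t matter.

#' Binomial variance of a hold-out accuracy estimate
#'
#' Variance of the proportion-correct estimate from a test set of
#' `test_size` independent samples when the classifier's true accuracy is
#' `accuracy`: `accuracy * (1 - accuracy) / test_size`.
#'
#' @param accuracy True accuracy in \[0, 1\].
#' @param test_size Number of test samples (>= 1).
#' @return Scalar variance.
#' @export
binomial_variance <- function(accuracy, test_size) {
  if (any(accuracy < 0 | accuracy > 1) || anyNA(accuracy)) {
    stop("'accuracy' must lie in [0, 1]")
  }
  if (any(test_size < 1)) stop("'test_size' must be a positive integer")
  accuracy * (1 - accuracy) / test_size
}

#' Variance of true accuracy across training sets
#'
#' Sample variance (denominator `R - 1`) of the true accuracies of
#' classifiers developed on different random training sets of the same
#' size — the accuracy-variance component of the MSE decomposition.
#'
#' @param true_accuracies Numeric vector of at least 2 accuracies.
#' @return Scalar sample variance.
#' @export
accuracy_variance <- function(true_accuracies) {
  if (length(true_accuracies) < 2L) stop("need at least 2 accuracies")
  stats::var(true_accuracies)
}

#' Squared bias of training on t rather than n samples
#'
#' @param mean_accuracy_t Mean true accuracy of classifiers trained on `t`
#'   samples, in \[0, 1\].
#' @param mean_accuracy_n Mean true accuracy of the classifier trained on
#'   all `n` samples, in \[0, 1\].
#' @return `(mean_accuracy_t - mean_accuracy_n)^2`.
#' @export
squared_bias <- function(mean_accuracy_t, mean_accuracy_n) {
  if (any(c(mean_accuracy_t, mean_accuracy_n) < 0) ||
      any(c(mean_accuracy_t, mean_accuracy_n) > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  (mean_accuracy_t - mean_accuracy_n)^2
}

#' Assemble an MSE decomposition over a training-size grid
#'
#' Combines per-`t` components into `mse = A + V + B` (exact, elementwise)
#' and `rmse = sqrt(mse)`.  When the variance contribution was estimated as
#' a single composite (the nonparametric bootstrap estimates `A + V`
#' jointly), pass it as `A` with `V = 0` and set
#' `variance_components = "composite"`; the printed table then labels the
#' column accordingly.
#'
#' @param n Total sample size.
#' @param grid Training sizes, strictly increasing, within `[1, n - 1]`.
#' @param A Accuracy-variance component per `t` (or the `A + V` composite).
#' @param V Binomial-variance component per `t`.
#' @param B Squared-bias component per `t`.
#' @param variance_components `"separate"` (default) or `"composite"`.
#' @return Object of class `"mse_decomposition"`: a list with `n`, `grid`,
#'   `A`, `V`, `B`, `mse`, `rmse` and the `variance_components` marker.
#' @export
mse_decomposition <- function(n, grid, A, V, B,
                              variance_components = c("separate", "composite")) {
  variance_components <- match.arg(variance_components)
  k <- length(grid)
  if (k == 0L) stop("'grid' must be non-empty")
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (min(grid) < 1 || max(grid) > n - 1) stop("'grid' must lie within [1, n - 1]")
  if (length(A) != k || length(V) != k || length(B) != k) {
    stop("'A', 'V' and 'B' must each have one value per grid point")
  }
  if (anyNA(c(A, V, B)) || any(c(A, V, B) < 0)) {
    stop("decomposition components must be non-negative")
  }
  mse <- A + V + B
  structure(
    list(n = as.integer(n), grid = as.integer(grid),
         A = A, V = V, B = B, mse = mse, rmse = sqrt(mse),
         variance_components = variance_components),
    class = "mse_decomposition"
  )
}

#' @export
as.data.frame.mse_decomposition <- function(x, ...) {
  data.frame(t = x$grid, A = x$A, V = x$V, B = x$B, MSE = x$mse, RMSE = x$rmse)
}

#' @export
print.mse_decomposition <- function(x, ...) {
  cat(sprintf("MSE decomposition over %d training sizes (n = %d)%s\n",
              length(x$grid), x$n,
              if (x$variance_components == "composite")
                " [A column holds the bootstrap A+V composite]" else ""))
  print(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (length(x$grid) > 12) cat("  ...\n")
  invisible(x)
}

#' Recommend a split from an MSE decomposition
#'
#' Finds the training size minimizing the RMSE (ties broken toward the
#' smaller `t`, i.e. the larger test set), the plateau of practically
#' equivalent sizes (RMSE within `plateau_tol` of the minimum), and the
#' excess error of the two common rules of thumb: allocating 1/2 or 2/3 of
#' the samples to training, each evaluated at the nearest grid point.
#'
#' @param decomp An [mse_decomposition()].
#' @param plateau_tol Plateau tolerance in RMSE units; the default 0.001 is
#'   an excess error small enough to be comparable to adding a handful of
#'   binomial test samples.
#' @param full_data_accuracy Accuracy (in \[0, 1\]) of the classifier
#'   developed on all `n` samples, carried into the report.
#' @return Object of class `"split_recommendation"`: `t_opt`, `plateau`
#'   (integer vector), `plateau_to_max` (does the plateau reach the largest
#'   grid point?), `excess_half`, `excess_twothirds`, `t_half`,
#'   `t_twothirds`, `full_data_accuracy`, `n`.
#' @export
summarize_mse <- function(decomp, plateau_tol = 0.001, full_data_accuracy = NA_real_) {
  stopifnot(inherits(decomp, "mse_decomposition"))
  if (plateau_tol < 0) stop("'plateau_tol' must be non-negative")
  grid <- decomp$grid
  rmse <- decomp$rmse
  i_opt <- which.min(rmse)  # first minimum = smallest t on ties
  plateau <- grid[rmse - rmse[i_opt] <= plateau_tol]
  i_half <- which.min(abs(grid - round(decomp$n / 2)))
  i_23 <- which.min(abs(grid - round(2 * decomp$n / 3)))
  structure(
    list(
      t_opt = grid[i_opt],
      plateau = plateau,
      plateau_to_max = max(plateau) == max(grid),
      excess_half = rmse[i_half] - rmse[i_opt],
      excess_twothirds = rmse[i_23] - rmse[i_opt],
      t_half = grid[i_half],
      t_twothirds = grid[i_23],
      full_data_accuracy = full_data_accuracy,
      n = decomp$n
    ),
    class = "split_recommendation"
  )
}

#' @export
print.split_recommendation <- function(x, ...) {
  cat(sprintf("Optimal split for n = %d: t = %d training / %d test%s\n",
              x$n, x$t_opt, x$n - x$t_opt,
              if (x$plateau_to_max) sprintf(" (plateau %d+)", min(x$plateau)) else ""))
  if (!is.na(x$full_data_accuracy)) {
    cat(sprintf("  full-data classifier accuracy: %.3f\n", x$full_data_accuracy))
  }
  cat(sprintf("  excess error at t = %d (1/2 rule):  %.4f\n", x$t_half, x$excess_half))
  cat(sprintf("  excess error at t = %d (2/3 rule):  %.4f\n", x$t_twothirds, x$excess_twothirds))
  invisible(x)
}

#' Write / read an MSE decomposition as tab-delimited text
#'
#' Six columns: `t`, `A`, `V`, `B`, `MSE`, `RMSE`.
#'
#' @param decomp An [mse_decomposition()].
#' @param path File path.
#' @return `write_decomposition` returns `path` invisibly;
#'   `read_decomposition` returns the decomposition table as a data frame.
#' @export
write_decomposition <- function(decomp, path) {
  utils::write.table(as.data.frame(decomp), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  df <- utils::read.delim(path)
  expected <- c("t", "A", "V", "B", "MSE", "RMSE")
  if (!identical(names(df), expected)) {
    stop("decomposition file must have columns: ", paste(expected, collapse = ", "))
  }
  df
}
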