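#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact confidence interval for a binomial success probability,
#' obtained by inverting the binomial tail probabilities (computed through
#' the beta-quantile representation).  Used to express the uncertainty of a
#' classification-accuracy estimate based on a test set of a given size:
#' with only 10 test samples, even a perfect 10/10 result has a 95% interval
#' reaching down to roughly 69%.
#'
#' @param successes Number of successes (correctly classified test samples).
#' @param trials Number of trials (test-set size), a positive integer.
#' @param conf_level Confidence level, a value in (0, 1). Default 0.95.
#'
#' @return An object of class `"binomial_interval"`: a list with elements
#'   `successes`, `trials`, `conf_level`, `estimate`, `lower` and `upper`.
#'   `lower` is 0 when `successes == 0` and `upper` is 1 when
#'   `successes == trials`.
#'
#' @examples
#' ci <- clopper_pearson(10, 10, 0.95)
#' ci$lower  # about 0.69
#' @export
clopper_pearson <- function(successes, trials, conf_level = 0.95) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes < 0 || trials < 1 ||
      successes != round(successes) || trials != round(trials)) {
    stop("'successes' must be a non-negative integer and 'trials' a positive integer")
  }
  if (successes > trials) {
    stop("'successes' cannot exceed 'trials'")
  }
  if (length(conf_level) != 1L || is.na(conf_level) ||
      conf_level <= 0 || conf_level >= 1) {
    stop("'conf_level' must be a single value strictly between 0 and 1")
  }
  a <- (1 - conf_level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  structure(
    list(
      successes = as.integer(successes),
      trials = as.integer(trials),
      conf_level = conf_level,
      estimate = successes / trials,
      lower = lower,
      upper = upper
    ),
    class = "binomial_interval"
  )
}

#' @export
print.binomial_interval <- function(x, ...) {
  cat(sprintf(
    "Exact binomial interval: %d/%d = %.3f, %d%% CI [%.4f, %.4f]\n",
    x$successes, x$trials, x$estimate,
    round(100 * x$conf_level), x$lower, x$upper
  ))
  invisible(x)
}

#' Weighted monotone regression (pool-adjacent-violators)
#'
#' Weighted least-squares projection of a sequence onto the cone of
#' nondecreasing (or nonincreasing) sequences, via the classic
#' pool-adjacent-violators algorithm.  Pooled blocks carry their weighted
#' mean.  In this package it backs the monotone fallback of
#' [fit_error_curve()]: classification error is forced to be nonincreasing
#' in the training-set size when a smooth fit wiggles upward.
#'
#' @param values Numeric vector to be projected (length >= 1).
#' @param weights Positive case weights, same length as `values`.
#'   Default: unit weights.
#' @param direction `"nondecreasing"` or `"nonincreasing"`.
#'
#' @return Numeric vector of fitted values, monotone in the requested
#'   direction, minimizing `sum(weights * (values - fit)^2)`.
#' @export
pava_monotone <- function(values, weights = NULL,
                          direction = c("nondecreasing", "nonincreasing")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n == 0L) stop("'values' must have length >= 1")
  if (anyNA(values)) stop("'values' must not contain missing values")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("'weights' must have the same length as 'values'")
  if (anyNA(weights) || any(weights <= 0)) stop("'weights' must be positive")
  if (direction == "nonincreasing") {
    return(-pava_monotone(-values, weights, "nondecreasing"))
  }
  # stack of blocks: value (weighted mean), weight, count
  bv <- numeric(n)
  bw <- numeric(n)
  bn <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    bv[k] <- values[i]
    bw[k] <- weights[i]
    bn[k] <- 1L
    while (k > 1L && bv[k - 1L] > bv[k]) {
      w <- bw[k - 1L] + bw[k]
      bv[k - 1L] <- (bw[k - 1L] * bv[k - 1L] + bw[k] * bv[k]) / w
      bw[k - 1L] <- w
      bn[k - 1L] <- bn[k - 1L] + bn[k]
      k <- k - 1L
    }
  }
  rep.int(bv[seq_len(k)], bn[seq_len(k)])
}

#' Fit a smoothed learning curve of error rate on training size
#'
#' Fits a weighted smoothing spline of mean error rate on training-set size
#' `t`, with case weights `1/t` (small training sets are based on noisier
#' classifiers, so they are down-weighted).  If the resulting fitted curve is
#' not nonincreasing in `t` (any fitted increase above `1e-6` between
#' consecutive grid points), the fit falls back to weighted isotonic
#' regression in the nonincreasing direction.  The fitted curve is evaluated
#' on the observed grid and additionally at `t = n`: the spline extrapolates
#' linearly beyond the last observed point (the natural-spline boundary
#' behaviour), while the isotonic fit extends flat.
#'
#' The spline's degrees of freedom default to the generalized
#' cross-validation choice, capped at `min(6, length(grid) - 2)` so that a
#' short noisy grid cannot be interpolated; pass `smoothing_df` to override.
#'
#' @param grid Strictly increasing positive integer training sizes, all
#'   below `n`; at least 4 points.
#' @param raw_values Mean error rates in \[0, 1\], one per grid point.
#' @param n Total sample size; the curve is also evaluated here.
#' @param smoothing_df Optional spline degrees of freedom (> 1).  `NULL`
#'   (default) uses GCV with the cap described above.
#'
#' @return An object of class `"curve_fit"`: list with `grid`, `raw_values`,
#'   `case_weights`, `eval_grid` (grid plus `n`), `fitted_values` (clamped
#'   to \[0, 1\]), `method_used` (`"spline"` or `"isotonic"`), `df_used`
#'   (NA for the isotonic path) and `n`.
#' @seealso [pava_monotone()]
#' @export
fit_error_curve <- function(grid, raw_values, n, smoothing_df = NULL) {
  if (length(grid) < 4L) stop("need at least 4 grid points to smooth")
  if (length(raw_values) != length(grid)) {
    stop("'raw_values' must have one value per grid point")
  }
  if (anyNA(grid) || any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (max(grid) >= n) stop("all grid points must be below 'n'")
  if (anyNA(raw_values) || any(raw_values < 0 | raw_values > 1)) {
    stop("'raw_values' must lie in [0, 1]")
  }
  w <- 1 / grid
  df_cap <- min(6, length(grid) - 2)
  fit <- stats::smooth.spline(grid, raw_values, w = w, cv = FALSE)
  df_use <- if (is.null(smoothing_df)) min(fit$df, df_cap) else smoothing_df
  df_use <- max(df_use, 1.05)
  if (abs(df_use - fit$df) > 1e-8) {
    fit <- stats::smooth.spline(grid, raw_values, w = w, df = df_use)
  }
  fitted_grid <- stats::predict(fit, grid)$y
  if (any(diff(fitted_grid) > 1e-6)) {
    method <- "isotonic"
    df_use <- NA_real_
    fitted_grid <- pava_monotone(raw_values, weights = w, direction = "nonincreasing")
    fitted_n <- fitted_grid[length(fitted_grid)]
  } else {
    method <- "spline"
    fitted_n <- stats::predict(fit, n)$y
  }
  fitted <- pmin(pmax(c(fitted_grid, fitted_n), 0), 1)
  structure(
    list(
      grid = grid,
      raw_values = raw_values,
      case_weights = w,
      eval_grid = c(grid, n),
      fitted_values = fitted,
      method_used = method,
      df_used = df_use,
      n = n
    ),
    class = "curve_fit"
  )
}

#' Evaluate a fitted error curve
#'
#' Linear interpolation of the fitted curve on its evaluation grid; flat
#' beyond the ends (the isotonic extension; for the spline path the point
#' `t = n` is already part of the evaluation grid).
#'
#' @param object A `"curve_fit"` object from [fit_error_curve()].
#' @param t Training sizes at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of fitted error rates.
#' @export
predict.curve_fit <- function(object, t, ...) {
  stats::approx(object$eval_grid, object$fitted_values, xout = t, rule = 2)$y
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "Error-curve fit (%s%s) on %d training sizes in [%d, %d], n = %d\n",
    x$method_used,
    if (is.na(x$df_used)) "" else sprintf(", df = %.2f", x$df_used),
    length(x$grid), min(x$grid), max(x$grid), x$n
  ))
  cat(sprintf("  fitted error at t = n: %.4f\n", x$fitted_values[length(x$fitted_values)]))
  invisible(x)
}
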