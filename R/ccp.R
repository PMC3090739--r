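# Compound covariate predictor: pooled-variance t-test gene selection,
# t-statistic weights, midpoint cutpoint on the compound covariate.

.as_expr_labels <- function(x, labels = NULL) {
  if (inherits(x, "expression_dataset")) {
    list(expr = x$expr, labels = x$labels)
  } else {
    if (is.null(labels)) stop("'labels' must be supplied with a matrix input")
    d <- expression_dataset(as.matrix(x), labels)
    list(expr = d$expr, labels = d$labels)
  }
}

# Per-gene pooled-variance two-sample t statistics; numerator mean(class1) -
# mean(class2).  Zero pooled variance -> statistic 0, flagged.
.pooled_t_core <- function(expr, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- expr[, idx1, drop = FALSE]
  x2 <- expr[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  sp2 <- ss / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  zero <- se == 0
  tt[zero] <- 0
  attr(tt, "zero_variance") <- zero
  tt
}

#' Per-gene pooled-variance two-sample t statistics
#'
#' Classical two-sample t statistic with pooled variance for every gene,
#' on `n1 + n2 - 2` degrees of freedom.  The numerator is
#' `mean(class 1) - mean(class 2)`.  Genes whose pooled variance is exactly
#' zero receive statistic 0 and are flagged in the `"zero_variance"`
#' attribute (they are never selectable by [select_genes()]).
#'
#' @param x An `"expression_dataset"` or a genes-by-samples numeric matrix.
#' @param labels Class labels (required when `x` is a matrix).
#' @return Numeric vector of t statistics (one per gene), with attributes
#'   `"zero_variance"` (logical) and `"df"` (residual degrees of freedom).
#' @export
pooled_t <- function(x, labels = NULL) {
  d <- .as_expr_labels(x, labels)
  lv <- levels(d$labels)
  idx1 <- which(d$labels == lv[1])
  idx2 <- which(d$labels == lv[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("each class needs at least 2 samples for a pooled t-test")
  }
  tt <- .pooled_t_core(d$expr, idx1, idx2)
  attr(tt, "df") <- length(idx1) + length(idx2) - 2L
  tt
}

#' Select genes by two-sided t-test p-value cutoff
#'
#' Returns the indices of genes whose two-sided pooled-t p-value is at most
#' `alpha` (boundary included).  `alpha = 1` returns every gene with
#' positive pooled variance; zero-variance genes are never selected.
#'
#' @param t_stats Per-gene t statistics, as from [pooled_t()].
#' @param alpha Significance cutoff in (0, 1].
#' @param df Residual degrees of freedom; defaults to the `"df"` attribute
#'   of `t_stats`.
#' @return Integer vector of selected gene indices.
#' @export
select_genes <- function(t_stats, alpha, df = attr(t_stats, "df")) {
  if (is.null(df)) stop("'df' must be supplied when 't_stats' carries no df attribute")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be a single value in (0, 1]")
  }
  pv <- 2 * stats::pt(-abs(as.numeric(t_stats)), df)
  sel <- pv <= alpha
  zero <- attr(t_stats, "zero_variance")
  if (!is.null(zero)) sel <- sel & !zero
  unname(which(sel))
}

# Assemble a ccp_model from precomputed statistics (hot path used by the
# simulation engines; skips re-deriving t statistics per alpha).
.ccp_from_stats <- function(tt, expr, idx1, idx2, alpha, lv, df) {
  zero <- attr(tt, "zero_variance")
  pv <- 2 * stats::pt(-abs(tt), df)
  keep <- pv <= alpha
  if (!is.null(zero)) keep <- keep & !zero
  sel <- unname(which(keep))
  if (length(sel) == 0L) {
    fallback <- if (length(idx1) >= length(idx2)) lv[1] else lv[2]
    return(structure(
      list(selected_genes = integer(0), weights = numeric(0),
           cutpoint = NA_real_, high_class = NA_character_,
           fallback_class = fallback, class_levels = lv,
           alpha_used = alpha, df = df, p = nrow(expr)),
      class = "ccp_model"
    ))
  }
  w <- as.numeric(tt[sel])
  cc <- colSums(expr[sel, , drop = FALSE] * w)
  c1 <- mean(cc[idx1])
  c2 <- mean(cc[idx2])
  structure(
    list(selected_genes = sel, weights = w,
         cutpoint = (c1 + c2) / 2,
         high_class = if (c1 >= c2) lv[1] else lv[2],
         fallback_class = NA_character_, class_levels = lv,
         alpha_used = alpha, df = df, p = nrow(expr)),
    class = "ccp_model"
  )
}

#' Fit a compound covariate predictor
#'
#' Selects genes by pooled-variance t-tests at significance cutoff `alpha`,
#' then forms the compound covariate `c(x) = sum_j t_j x_j` over the
#' selected genes, using the t statistics themselves as weights.  The
#' classification cutpoint `k` is the midpoint of the two training-class
#' means of the compound covariate; samples scoring at or above `k` are
#' assigned to the class whose training mean lies on the high side.  When no
#' gene passes the cutoff the model degenerates to a majority-class rule
#' (ties broken toward class 1, the first factor level).
#'
#' @param x An `"expression_dataset"` or genes-by-samples matrix.
#' @param labels Class labels (matrix input only).
#' @param alpha Gene-selection significance cutoff in (0, 1].
#' @return An object of class `"ccp_model"` with elements `selected_genes`,
#'   `weights`, `cutpoint`, `high_class`, `fallback_class`, `class_levels`,
#'   `alpha_used`, `df` and `p`.
#' @examples
#' sc <- simulation_scenario(n = 60, p = 200, m = 10, effect = 1.5)
#' d <- simulate_dataset(sc, seed = 1)
#' fit <- fit_ccp(d, alpha = 0.001)
#' mean(predict(fit, d) == d$labels)  # training accuracy
#' @export
fit_ccp <- function(x, labels = NULL, alpha = 0.001) {
  d <- .as_expr_labels(x, labels)
  lv <- levels(d$labels)
  idx1 <- which(d$labels == lv[1])
  idx2 <- which(d$labels == lv[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("each class needs at least 2 training samples")
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must be a single value in (0, 1]")
  }
  tt <- .pooled_t_core(d$expr, idx1, idx2)
  .ccp_from_stats(tt, d$expr, idx1, idx2, alpha, lv, length(idx1) + length(idx2) - 2L)
}

#' @export
print.ccp_model <- function(x, ...) {
  if (length(x$selected_genes) == 0L) {
    cat(sprintf("CCP model: no genes at alpha = %g; majority fallback -> class '%s'\n",
                x$alpha_used, x$fallback_class))
  } else {
    cat(sprintf(
      "CCP model: %d genes at alpha = %g, cutpoint k = %.4f, high side -> class '%s'\n",
      length(x$selected_genes), x$alpha_used, x$cutpoint, x$high_class
    ))
  }
  invisible(x)
}

#' Predict class labels with a compound covariate predictor
#'
#' Computes the compound covariate for each sample and assigns the class on
#' the side of the cutpoint `k`; a score exactly equal to `k` goes to the
#' high side.  A no-gene fallback model labels every sample with its
#' majority class.
#'
#' @param object A `"ccp_model"`.
#' @param newdata An `"expression_dataset"` or genes-by-samples matrix
#'   covering all selected gene indices (same gene order as at training).
#' @param ... Unused.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict.ccp_model <- function(object, newdata, ...) {
  expr <- if (inherits(newdata, "expression_dataset")) newdata$expr else as.matrix(newdata)
  if (!is.numeric(expr) || anyNA(expr)) stop("'newdata' must be numeric with no missing values")
  lv <- object$class_levels
  if (length(object$selected_genes) == 0L) {
    return(factor(rep(object$fallback_class, ncol(expr)), levels = lv))
  }
  if (nrow(expr) < max(object$selected_genes)) {
    stop("'newdata' does not cover all selected gene indices")
  }
  cc <- colSums(expr[object$selected_genes, , drop = FALSE] * object$weights)
  low_class <- setdiff(lv, object$high_class)
  factor(ifelse(cc >= object$cutpoint, object$high_class, low_class), levels = lv)
}

# Core of the theoretical-accuracy computation, on precomputed pieces:
# selected indices, weights, cutpoint, orientation sign, scenario.
.true_acc_core <- function(sel, w, k, high_is_class1, scenario) {
  m <- scenario$m
  delta <- scenario$effect * scenario$sigma / 2
  prev <- scenario$prevalence
  inf <- sel <= m
  wmu1 <- sum(w[inf]) * delta
  wmu2 <- -wmu1
  kind <- scenario$covariance$kind
  sig2 <- if (kind == "identity") {
    scenario$sigma^2 * sum(w^2)
  } else if (kind == "block") {
    rho <- scenario$covariance$rho
    wi <- w[inf]
    scenario$sigma^2 * (sum(w^2) + rho * (sum(wi)^2 - sum(wi^2)))
  } else {
    Sigma <- scenario$sigma^2 *
      build_covariance(scenario$covariance, scenario$p, m)[sel, sel, drop = FALSE]
    as.numeric(w %*% Sigma %*% w)
  }
  if (sig2 <= 0) stop("degenerate rule: the compound covariate has zero variance")
  sc <- sqrt(sig2)
  s <- if (high_is_class1) 1 else -1
  prev * stats::pnorm(s * (wmu1 - k) / sc) +
    (1 - prev) * stats::pnorm(s * (k - wmu2) / sc)
}

#' Exact accuracy of a fitted linear rule under a known scenario
#'
#' The probability that the fitted compound covariate rule classifies a new
#' sample correctly, computed in closed form under the scenario's two
#' multivariate normals: the compound covariate is univariate normal within
#' each class, so the accuracy is the prevalence-weighted pair of normal
#' tail probabilities of `(w'mu - k) / sqrt(w' Sigma w)`.  Available only in
#' simulation studies, where the generating parameters are known.  A no-gene
#' fallback model has accuracy equal to the prevalence of its fallback
#' class.
#'
#' @param model A `"ccp_model"` (or any list with the same fields) fitted to
#'   data simulated from `scenario`, with gene indices aligned to the
#'   scenario's gene order.
#' @param scenario The generating [simulation_scenario()].
#' @return Scalar accuracy in \[0, 1\].
#' @export
true_accuracy <- function(model, scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  lv <- model$class_levels
  if (length(model$selected_genes) == 0L) {
    return(if (model$fallback_class == lv[1]) scenario$prevalence else 1 - scenario$prevalence)
  }
  if (max(model$selected_genes) > scenario$p) {
    stop("model gene indices exceed the scenario's gene count")
  }
  .true_acc_core(model$selected_genes, model$weights, model$cutpoint,
                 model$high_class == lv[1], scenario)
}

#' Choose the gene-selection significance cutoff
#'
#' Picks the significance level `alpha` for t-test gene selection that
#' maximizes expected classification accuracy at a given training-set size.
#' Two modes:
#'
#' * **parametric** (`x` is a scenario): for each candidate `alpha`, the
#'   expected exact accuracy of a compound covariate predictor trained on
#'   `train_size` cases is estimated by Monte Carlo over `n_mc` simulated
#'   training sets; the maximizing `alpha` is returned.
#' * **data** (`x` is a dataset): `alpha` is chosen by stratified
#'   `folds`-fold cross-validated accuracy on the supplied data.  Class
#'   prevalence is implicitly estimated from the data, never assumed known.
#'
#' Ties (including the exactly flat accuracy profile of a no-signal
#' scenario with equal prevalence) are broken toward the smaller `alpha`,
#' i.e. the sparser model.
#'
#' @param train_size Training-set size the cutoff is optimized for
#'   (parametric mode; ignored in data mode).
#' @param x A [simulation_scenario()] or an `"expression_dataset"`.
#' @param alpha_grid Candidate cutoffs in (0, 1].
#' @param n_mc Monte Carlo training-set draws per candidate (parametric
#'   mode).
#' @param folds Number of cross-validation folds (data mode).
#' @param seed Optional seed for the internal randomization.
#' @return The selected `alpha` (scalar), with the per-candidate mean
#'   accuracies in the `"mean_accuracy"` attribute.
#' @export
optimal_alpha <- function(train_size, x,
                          alpha_grid = c(1e-6, 1e-5, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1),
                          n_mc = 50, folds = 5, seed = NULL) {
  if (length(alpha_grid) == 0L) stop("'alpha_grid' must be non-empty")
  if (any(alpha_grid <= 0 | alpha_grid > 1)) stop("'alpha_grid' values must be in (0, 1]")
  alpha_grid <- sort(alpha_grid)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "simulation_scenario")) {
    acc <- .optimal_alpha_parametric(train_size, x, alpha_grid, n_mc)
  } else if (inherits(x, "expression_dataset")) {
    acc <- .optimal_alpha_cv(x, alpha_grid, folds)
  } else {
    stop("'x' must be a simulation_scenario or an expression_dataset")
  }
  best <- alpha_grid[which.max(acc)]  # first max = smallest alpha on a tie
  structure(best, mean_accuracy = stats::setNames(acc, format(alpha_grid)))
}

.optimal_alpha_parametric <- function(train_size, scenario, alpha_grid, n_mc) {
  sub <- simulation_scenario(
    n = train_size, p = scenario$p, m = scenario$m, effect = scenario$effect,
    prevalence = scenario$prevalence, covariance = scenario$covariance,
    sigma = scenario$sigma, class_labels = scenario$class_labels
  )
  acc <- matrix(NA_real_, n_mc, length(alpha_grid))
  for (r in seq_len(n_mc)) {
    d <- simulate_dataset(sub)
    lv <- levels(d$labels)
    idx1 <- which(d$labels == lv[1])
    idx2 <- which(d$labels == lv[2])
    tt <- .pooled_t_core(d$expr, idx1, idx2)
    df <- length(idx1) + length(idx2) - 2L
    for (j in seq_along(alpha_grid)) {
      mod <- .ccp_from_stats(tt, d$expr, idx1, idx2, alpha_grid[j], lv, df)
      acc[r, j] <- true_accuracy(mod, scenario)
    }
  }
  colMeans(acc)
}

.optimal_alpha_cv <- function(dataset, alpha_grid, folds) {
  labels <- dataset$labels
  n <- length(labels)
  folds <- min(folds, min(table(labels)))
  if (folds < 2) stop("too few samples per class for cross-validation")
  fold_id <- integer(n)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- matrix(NA_real_, folds, length(alpha_grid))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    sub <- dataset$expr[, tr, drop = FALSE]
    lv <- levels(labels)
    idx1 <- which(labels[tr] == lv[1])
    idx2 <- which(labels[tr] == lv[2])
    tt <- .pooled_t_core(sub, idx1, idx2)
    df <- length(idx1) + length(idx2) - 2L
    for (j in seq_along(alpha_grid)) {
      mod <- .ccp_from_stats(tt, sub, idx1, idx2, alpha_grid[j], lv, df)
      pred <- predict(mod, dataset$expr[, te, drop = FALSE])
      acc[f, j] <- mean(pred == labels[te])
    }
  }
  colMeans(acc)
}
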