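#' Describe a two-class high-dimensional simulation scenario
#'
#' A complete parametric description of a two-class population of
#' log-expression profiles: each sample is a `p`-vector drawn from a
#' multivariate normal with class-specific mean and common covariance.
#' The first `m` genes are differentially expressed with a class-mean
#' difference of `effect * sigma` (the standardized fold change is the mean
#' difference divided by the within-class standard deviation); the remaining
#' `p - m` genes carry no signal.
#'
#' @param n Total number of samples (>= 4).
#' @param p Number of genes.
#' @param m Number of informative (differentially expressed) genes, `<= p`.
#' @param effect Standardized fold change: class-mean difference in units of
#'   the within-class standard deviation (>= 0).
#' @param prevalence Proportion of samples in class 1, in (0, 1). Class
#'   sizes are fixed at `round(prevalence * n)` and the complement.
#' @param covariance Covariance specification: `"identity"` (independent
#'   genes, the default), a supplied `p x p` covariance matrix, or one of the
#'   constructors [cov_shrunken()] / [cov_block()].
#' @param sigma Within-class standard deviation scale (default 1); the full
#'   covariance used for simulation is `sigma^2` times the matrix implied by
#'   `covariance`.
#' @param class_labels Length-2 character vector of class labels
#'   (class 1 first).
#'
#' @return An object of class `"simulation_scenario"`.
#' @examples
#' sc <- simulation_scenario(n = 100, p = 500, m = 10, effect = 1.0)
#' sc
#' @export
simulation_scenario <- function(n, p, m, effect, prevalence = 0.5,
                                covariance = "identity", sigma = 1,
                                class_labels = c("A", "B")) {
  if (n < 4) stop("'n' must be at least 4")
  if (m > p) stop("'m' cannot exceed 'p'")
  if (m < 0 || p < 1) stop("'m' must be >= 0 and 'p' >= 1")
  if (effect < 0) stop("'effect' must be non-negative")
  if (prevalence <= 0 || prevalence >= 1) stop("'prevalence' must be in (0, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (length(class_labels) != 2L || anyDuplicated(class_labels)) {
    stop("'class_labels' must be two distinct labels")
  }
  spec <- .normalize_cov_spec(covariance, p)
  n1 <- round(prevalence * n)
  if (n1 < 2 || n - n1 < 2) stop("scenario implies fewer than 2 samples in a class")
  structure(
    list(
      n = as.integer(n), p = as.integer(p), m = as.integer(m),
      effect = effect, prevalence = prevalence,
      covariance = spec, sigma = sigma,
      class_labels = as.character(class_labels)
    ),
    class = "simulation_scenario"
  )
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "Two-class scenario: n = %d (prevalence %.2f), p = %d genes, m = %d informative,\n  standardized fold change %.2f, covariance: %s, sigma = %g\n",
    x$n, x$prevalence, x$p, x$m, x$effect, x$covariance$kind, x$sigma
  ))
  invisible(x)
}

#' Shrunken covariance specification
#'
#' Shrinks a covariance matrix `S` toward its diagonal:
#' `rho * Diag(S) + (1 - rho) * S`, where `Diag(S)` is zero except for the
#' diagonal of `S`.  Shrinkage pulls a (possibly singular) sample covariance
#' away from singularity while preserving its gene-wise variances.
#'
#' @param rho Shrinkage weight in \[0, 1\]; 1 gives the pure diagonal.
#' @param S Symmetric covariance matrix with positive diagonal.
#' @return A covariance specification usable in [simulation_scenario()] and
#'   [build_covariance()].
#' @export
cov_shrunken <- function(rho, S) {
  list(kind = "shrunken", rho = rho, S = S)
}

#' Equicorrelated-block covariance specification
#'
#' Informative genes (the first `m` of the scenario) share a common pairwise
#' correlation `rho`; all other genes are independent with unit variance.
#' Correlation among the differentially expressed genes changes how much
#' independent evidence the informative genes carry, and hence the optimal
#' split.
#'
#' @param rho Common correlation among informative genes, in \[0, 1).
#' @return A covariance specification.
#' @export
cov_block <- function(rho) {
  list(kind = "block", rho = rho)
}

.normalize_cov_spec <- function(covariance, p) {
  if (is.character(covariance) && length(covariance) == 1L) {
    if (covariance != "identity") stop("unknown covariance keyword: ", covariance)
    return(list(kind = "identity"))
  }
  if (is.matrix(covariance)) {
    .check_symmetric(covariance, p)
    return(list(kind = "supplied", S = covariance))
  }
  if (is.list(covariance) && !is.null(covariance$kind)) {
    if (covariance$kind == "shrunken") {
      if (is.null(covariance$rho) || covariance$rho < 0 || covariance$rho > 1) {
        stop("shrinkage weight 'rho' must lie in [0, 1]")
      }
      .check_symmetric(covariance$S, p)
      if (any(diag(covariance$S) <= 0)) stop("'S' must have a positive diagonal")
      return(covariance)
    }
    if (covariance$kind == "block") {
      if (is.null(covariance$rho) || covariance$rho < 0 || covariance$rho >= 1) {
        stop("block correlation 'rho' must lie in [0, 1)")
      }
      return(covariance)
    }
    if (covariance$kind %in% c("identity", "supplied")) return(covariance)
  }
  stop("unrecognized covariance specification")
}

.check_symmetric <- function(S, p) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("covariance matrix must be square")
  if (!is.null(p) && nrow(S) != p) stop("covariance matrix dimension must equal 'p'")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("covariance matrix must be symmetric")
  }
  invisible(TRUE)
}

#' Construct the covariance matrix of a scenario specification
#'
#' Materializes the covariance implied by a specification: the identity,
#' a supplied matrix, the diagonal-shrunken combination
#' `rho * Diag(S) + (1 - rho) * S`, or an equicorrelated block among the
#' first `m` genes.  The result is checked for positive semi-definiteness.
#'
#' @param spec `"identity"`, a matrix, or a [cov_shrunken()] / [cov_block()]
#'   specification.
#' @param p Matrix dimension (number of genes).
#' @param m Number of informative genes (needed for `"block"` only).
#' @return A `p x p` covariance matrix.
#' @examples
#' build_covariance(cov_shrunken(0.9, matrix(c(1, .8, .8, 1), 2)), p = 2)
#' @export
build_covariance <- function(spec, p, m = 0L) {
  spec <- .normalize_cov_spec(spec, p)
  Sigma <- switch(spec$kind,
    identity = diag(p),
    supplied = spec$S,
    shrunken = {
      S <- spec$S
      spec$rho * diag(diag(S), nrow = nrow(S)) + (1 - spec$rho) * S
    },
    block = {
      Sigma <- diag(p)
      if (m > 1) {
        Sigma[seq_len(m), seq_len(m)] <- spec$rho
        diag(Sigma)[seq_len(m)] <- 1
      }
      Sigma
    }
  )
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("constructed covariance matrix is not positive semi-definite")
  }
  Sigma
}

#' Simulate a two-class expression dataset from a scenario
#'
#' Draws a genes-by-samples matrix of log expression from the scenario's
#' multivariate normal model.  Class sizes are fixed (`round(prevalence*n)`
#' in class 1), informative genes are placed at indices `1..m` with class
#' means `+effect*sigma/2` (class 1) and `-effect*sigma/2` (class 2), and the
#' true generating parameters are recorded in the `truth` element so that
#' downstream diagnostics can score gene selection.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional integer seed; the draw is deterministic given
#'   `scenario` and `seed`.  `NULL` uses (and advances) the current RNG
#'   stream.
#' @return An object of class `"expression_dataset"`: list with `expr`
#'   (`p x n` numeric matrix with gene/sample dimnames), `labels` (factor of
#'   length `n`, class 1 = first level) and `truth` (scenario plus the
#'   informative gene indices).
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n
  p <- scenario$p
  m <- scenario$m
  sigma <- scenario$sigma
  n1 <- round(scenario$prevalence * n)
  n2 <- n - n1
  delta <- scenario$effect * sigma / 2
  kind <- scenario$covariance$kind
  if (kind == "identity") {
    x <- matrix(stats::rnorm(p * n, sd = sigma), p, n)
  } else if (kind == "block") {
    x <- matrix(stats::rnorm(p * n, sd = sigma), p, n)
    rho <- scenario$covariance$rho
    if (m > 1 && rho > 0) {
      z <- stats::rnorm(n, sd = sigma)
      x[seq_len(m), ] <- sqrt(rho) * rep(z, each = m) +
        sqrt(1 - rho) * x[seq_len(m), , drop = FALSE]
    }
  } else {
    Sigma <- sigma^2 * build_covariance(scenario$covariance, p, m)
    R <- chol(Sigma, pivot = FALSE)
    x <- crossprod(R, matrix(stats::rnorm(p * n), p, n))
  }
  if (m > 0) {
    x[seq_len(m), seq_len(n1)] <- x[seq_len(m), seq_len(n1), drop = FALSE] + delta
    x[seq_len(m), n1 + seq_len(n2)] <- x[seq_len(m), n1 + seq_len(n2), drop = FALSE] - delta
  }
  rownames(x) <- sprintf("g%05d", seq_len(p))
  colnames(x) <- sprintf("s%04d", seq_len(n))
  labels <- factor(rep(scenario$class_labels, c(n1, n2)),
                   levels = scenario$class_labels)
  expression_dataset(x, labels,
                     truth = list(scenario = scenario,
                                  informative = seq_len(m),
                                  delta = delta))
}

#' Assemble an expression dataset object
#'
#' @param expr Numeric genes-by-samples matrix (log scale), no missing
#'   values.
#' @param labels Factor or character vector of per-sample class labels with
#'   exactly two distinct values; coerced to a factor whose first level is
#'   class 1.
#' @param truth Optional provenance (as recorded by [simulate_dataset()]).
#' @return An object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(expr, labels, truth = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("'expr' must be a numeric matrix")
  if (anyNA(expr)) stop("'expr' must not contain missing values")
  if (length(labels) != ncol(expr)) {
    stop("'labels' must have one entry per sample (column)")
  }
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  structure(list(expr = expr, labels = labels, truth = truth),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "Expression dataset: %d genes x %d samples (%s: %d, %s: %d)%s\n",
    nrow(x$expr), ncol(x$expr),
    names(tab)[1], tab[1], names(tab)[2], tab[2],
    if (is.null(x$truth)) "" else " [simulated]"
  ))
  invisible(x)
}
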