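# Shared fixtures and independent oracles for the test suite.

# Small, fast scenarios used across tests.
tiny_scenario <- function(n = 60, p = 200, m = 10, effect = 1.5, ...) {
  simulation_scenario(n = n, p = p, m = m, effect = effect, ...)
}

# Exact Clopper-Pearson endpoints by bisection on the binomial tail sums;
# independent of the beta-quantile route used by the implementation.
cp_bisect_oracle <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  bis <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bis(function(p) sum(stats::dbinom(x:n, n, p)) >= a, 0, x / n)
  upper <- if (x == n) 1 else bis(function(p) sum(stats::dbinom(0:x, n, p)) <= a, x / n, 1)
  c(lower = lower, upper = upper)
}

# Exact weighted monotone least squares by enumerating all consecutive
# block partitions (each block fitted at its weighted mean, kept only if
# the block means are monotone).  Exact for any input length; used on
# inputs of length <= 5.
pava_exhaustive_oracle <- function(values, weights, direction = "nondecreasing") {
  n <- length(values)
  if (direction == "nonincreasing") {
    return(-pava_exhaustive_oracle(-values, weights, "nondecreasing"))
  }
  best <- NULL
  best_sse <- Inf
  # each of the n-1 gaps is either a block boundary or not
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- sum(weights[idx] * values[idx]) / sum(weights[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# A cheap plug-in classifier for nonparametric tests: nearest class
# centroid on the top-variance gene subset is overkill; this one thresholds
# the single gene with the largest absolute pooled-t statistic.
single_gene_classifier <- function() {
  split_classifier(
    fit = function(expr, labels) {
      tt <- pooled_t(expr, labels)
      j <- which.max(abs(tt))
      lv <- levels(as.factor(labels))
      m1 <- mean(expr[j, labels == lv[1]])
      m2 <- mean(expr[j, labels == lv[2]])
      list(j = j, k = (m1 + m2) / 2, high = if (m1 >= m2) lv[1] else lv[2], lv = lv)
    },
    predict = function(model, expr) {
      low <- setdiff(model$lv, model$high)
      factor(ifelse(expr[model$j, ] >= model$k, model$high, low), levels = model$lv)
    },
    name = "single-gene"
  )
}
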