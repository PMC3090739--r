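# 4-sample toy with closed-form statistics: gene 1 has t = -2*sqrt(2),
# gene 2 has t = 4*sqrt(2); compound covariates are 18*sqrt(2) (class A)
# and 6*sqrt(2) (class B), so k = 12*sqrt(2).
toy_expr <- function() {
  matrix(c(1, 5,
           2, 5.5,
           3, 3,
           4, 3.5),
         nrow = 2, ncol = 4,
         dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
}
toy_labels <- factor(c("A", "A", "B", "B"))

test_that("pooled_t matches the textbook pooled-variance formula", {
  tt <- pooled_t(toy_expr(), toy_labels)
  expect_equal(unname(tt[1]), -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(unname(tt[2]), 4 * sqrt(2), tolerance = 1e-12)
  expect_identical(attr(tt, "df"), 2L)
  # location invariance
  tt_shift <- pooled_t(toy_expr() + 100, toy_labels)
  expect_equal(as.numeric(tt_shift), as.numeric(tt))
  # identical values in both classes -> t = 0, flagged
  flat <- rbind(rep(1, 4), toy_expr()[1, ])
  tt0 <- pooled_t(flat, toy_labels)
  expect_identical(unname(tt0[1]), 0)
  expect_true(attr(tt0, "zero_variance")[1])
  expect_error(pooled_t(toy_expr(), factor(rep("A", 4), levels = c("A", "B"))))
})

test_that("select_genes applies the two-sided cutoff with boundary inclusion", {
  tt <- pooled_t(toy_expr(), toy_labels)
  expect_identical(select_genes(tt, alpha = 1), c(1L, 2L))
  expect_identical(select_genes(tt, alpha = 1e-6), integer(0))
  # a gene whose p-value equals alpha exactly is included (<= rule)
  p1 <- 2 * pt(-abs(tt[1]), df = 2)
  expect_true(1L %in% select_genes(tt, alpha = p1))
  expect_false(1L %in% select_genes(tt, alpha = p1 * 0.999))
  # zero-variance genes are never selectable, even at alpha = 1
  flat <- rbind(rep(1, 4), toy_expr())
  tt0 <- pooled_t(flat, toy_labels)
  expect_false(1L %in% select_genes(tt0, alpha = 1))
})

test_that("fit_ccp reproduces the toy compound covariate by hand arithmetic", {
  fit <- fit_ccp(toy_expr(), toy_labels, alpha = 1)
  expect_identical(fit$selected_genes, c(1L, 2L))
  expect_equal(fit$weights, c(-2 * sqrt(2), 4 * sqrt(2)), tolerance = 1e-12)
  expect_equal(fit$cutpoint, 12 * sqrt(2), tolerance = 1e-12)
  expect_identical(fit$high_class, "A")
  # perfect separation: training accuracy 1
  expect_identical(as.character(predict(fit, toy_expr())), c("A", "A", "B", "B"))
  # a score exactly at the cutpoint goes to the high side
  x_at_k <- matrix(c(0, 12 * sqrt(2) / (4 * sqrt(2))), 2, 1)
  expect_identical(as.character(predict(fit, x_at_k)), "A")
})

test_that("empty selection falls back to the majority class", {
  set.seed(1)
  x <- matrix(rnorm(5 * 9), 5, 9)
  labels <- factor(c(rep("A", 4), rep("B", 5)))
  fit <- fit_ccp(x, labels, alpha = 1e-12)
  expect_length(fit$selected_genes, 0)
  expect_identical(fit$fallback_class, "B")
  expect_true(all(predict(fit, x) == "B"))
  # ties go to class 1 (first level)
  fit_tie <- fit_ccp(x[, 1:8], labels[1:8], alpha = 1e-12)
  expect_identical(fit_tie$fallback_class, "A")
  # fallback accuracy equals the prevalence of the fallback class
  sc <- simulation_scenario(n = 100, p = 5, m = 0, effect = 0, prevalence = 0.4,
                            class_labels = c("A", "B"))
  expect_equal(true_accuracy(fit, sc), 0.6)
})

test_that("true_accuracy matches closed-form anchor cases", {
  sc <- simulation_scenario(n = 100, p = 100, m = 1, effect = 2.0)
  rule <- function(sel, w, k, high = "A") {
    structure(list(selected_genes = sel, weights = w, cutpoint = k,
                   high_class = high, fallback_class = NA_character_,
                   class_levels = c("A", "B"), alpha_used = 1, df = 98, p = 100),
              class = "ccp_model")
  }
  # single informative gene, k at the true midpoint: Phi(delta/sigma) = Phi(1)
  expect_equal(true_accuracy(rule(1L, 3, 0), sc), pnorm(1), tolerance = 1e-12)
  # weights on noise genes only: no signal in the rule
  expect_equal(true_accuracy(rule(c(5L, 9L), c(1, -2), 0), sc), 0.5, tolerance = 1e-12)
  # 50 equally weighted informative genes at effect 1.0: Phi(sqrt(50)/2)
  sc50 <- simulation_scenario(n = 100, p = 100, m = 50, effect = 1.0)
  expect_equal(true_accuracy(rule(1:50, rep(1, 50), 0), sc50),
               pnorm(sqrt(50) / 2), tolerance = 1e-12)
  expect_gt(true_accuracy(rule(1:50, rep(1, 50), 0), sc50), 0.99)
  # degenerate rule: zero compound-covariate variance
  sc_deg <- simulation_scenario(n = 100, p = 2, m = 0, effect = 0,
                                covariance = matrix(c(1, 1, 1, 1), 2))
  expect_error(true_accuracy(rule(1:2, c(1, -1), 0), sc_deg), "degenerate")
})

test_that("true_accuracy agrees with Monte Carlo over random rules and scenarios", {
  set.seed(99)
  n_mc <- 1e5
  for (rep in 1:10) {
    p <- 30
    m <- sample(0:10, 1)
    effect <- runif(1, 0, 2)
    rho <- sample(c(0, 0.4), 1)
    cov <- if (rho == 0) "identity" else cov_block(rho)
    sc <- simulation_scenario(n = 100, p = p, m = m, effect = effect,
                              prevalence = sample(c(0.5, 0.35), 1),
                              covariance = cov)
    d <- simulate_dataset(sc)
    fit <- fit_ccp(d, alpha = sample(c(0.01, 0.1, 1), 1))
    if (length(fit$selected_genes) == 0) next
    acc <- true_accuracy(fit, sc)
    # Monte Carlo oracle: draw fresh samples from the generating model and
    # classify them with the fitted rule
    n1 <- rbinom(1, n_mc, sc$prevalence)
    Sigma <- build_covariance(sc$covariance, p, m)
    R <- chol(Sigma)
    xs <- crossprod(R, matrix(rnorm(p * n_mc), p, n_mc)) * sc$sigma
    delta <- sc$effect * sc$sigma / 2
    if (m > 0) {
      xs[1:m, 1:n1] <- xs[1:m, 1:n1] + delta
      xs[1:m, (n1 + 1):n_mc] <- xs[1:m, (n1 + 1):n_mc] - delta
    }
    truth <- rep(levels(d$labels), c(n1, n_mc - n1))
    acc_mc <- mean(predict(fit, xs) == truth)
    se <- sqrt(acc_mc * (1 - acc_mc) / n_mc) + 1e-6
    expect_lt(abs(acc - acc_mc), 5 * se + 0.005)
  }
})

test_that("adding pure-noise genes to a rule never increases true accuracy", {
  set.seed(5)
  sc <- simulation_scenario(n = 100, p = 50, m = 2, effect = 1.5)
  base <- structure(list(selected_genes = 1:2, weights = c(2, 3), cutpoint = 0,
                         high_class = "A", fallback_class = NA_character_,
                         class_levels = c("A", "B"), alpha_used = 1, df = 98, p = 50),
                    class = "ccp_model")
  acc0 <- true_accuracy(base, sc)
  for (rep in 1:20) {
    extra <- sample(3:50, sample(1:10, 1))
    diluted <- base
    diluted$selected_genes <- c(1:2, extra)
    # noise weights leave the class means of c symmetric, so k stays 0
    diluted$weights <- c(base$weights, rnorm(length(extra)))
    expect_lte(true_accuracy(diluted, sc), acc0 + 1e-12)
  }
})

test_that("optimal_alpha obeys its tie and degenerate-grid rules", {
  sc_null <- simulation_scenario(n = 40, p = 50, m = 0, effect = 0)
  # equal-prevalence null: every rule has exact accuracy 0.5, so the tie
  # rule returns the smallest candidate
  a <- optimal_alpha(30, sc_null, alpha_grid = c(0.1, 1e-4, 0.01), n_mc = 5, seed = 2)
  expect_equal(as.numeric(a), 1e-4)
  expect_true(all(abs(attr(a, "mean_accuracy") - 0.5) < 1e-12))
  # single-element grid is returned as-is
  expect_equal(as.numeric(optimal_alpha(30, sc_null, alpha_grid = 0.05, n_mc = 2)),
               0.05)
  expect_error(optimal_alpha(30, sc_null, alpha_grid = numeric(0)), "non-empty")
  expect_error(optimal_alpha(30, sc_null, alpha_grid = c(0.5, 2)), "\\(0, 1\\]")
})

test_that("optimal_alpha admits a strong informative gene and lifts accuracy", {
  sc <- simulation_scenario(n = 200, p = 500, m = 1, effect = 2.0)
  a <- as.numeric(optimal_alpha(100, sc, n_mc = 25, seed = 8))
  set.seed(9)
  sub <- simulation_scenario(n = 100, p = 500, m = 1, effect = 2.0)
  hits <- accs <- numeric(50)
  for (r in 1:50) {
    fit <- fit_ccp(simulate_dataset(sub), alpha = a)
    hits[r] <- 1L %in% fit$selected_genes
    accs[r] <- true_accuracy(fit, sc)
  }
  expect_gte(mean(hits), 0.99)
  expect_gte(mean(accs), 0.80)
})

test_that("data-mode optimal_alpha cross-validates on the supplied dataset", {
  sc <- simulation_scenario(n = 60, p = 300, m = 20, effect = 1.5)
  d <- simulate_dataset(sc, seed = 13)
  set.seed(14)
  a <- optimal_alpha(NA, d, alpha_grid = c(1e-4, 1e-3, 0.01, 0.1))
  expect_true(as.numeric(a) %in% c(1e-4, 1e-3, 0.01, 0.1))
  # strong signal: the chosen cutoff achieves high CV accuracy
  expect_gt(max(attr(a, "mean_accuracy")), 0.8)
})
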