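# Nonparametric resampling tests run on small simulated datasets with a
# cheap classifier where the classifier itself is not under test.

test_that("learning_curve estimates a decreasing error for a learnable dataset", {
  sc <- simulation_scenario(n = 100, p = 100, m = 50, effect = 2.0)
  d <- simulate_dataset(sc, seed = 1)
  lc <- learning_curve(d, ccp_classifier(0.01), n_splits = 30, seed = 2)
  expect_equal(lc$grid, seq(10L, 90L, 10L))
  f <- predict(lc$fit, lc$grid)
  expect_lte(f[length(f)], f[1])
  expect_true(all(lc$mean_error >= 0 & lc$mean_error <= 1))
})

test_that("learning_curve on permuted labels stays at chance error", {
  sc <- simulation_scenario(n = 80, p = 60, m = 20, effect = 1.5)
  d <- simulate_dataset(sc, seed = 3)
  set.seed(4)
  d_null <- expression_dataset(d$expr, sample(as.character(d$labels)))
  n_splits <- 40
  lc <- learning_curve(d_null, single_gene_classifier(), n_splits = n_splits, seed = 5)
  for (i in seq_along(lc$grid)) {
    # binomial-ish SE of a mean error over n_splits correlated splits;
    # conservative: treat each split's error as one draw of sd 0.5/sqrt(n-t)
    se <- 0.5 / sqrt(80 - lc$grid[i]) + 0.5 / sqrt(n_splits)
    expect_lt(abs(lc$mean_error[i] - 0.5), 3 * se + 0.05)
  }
})

test_that("learning_curve is reproducible and reports classifier failures", {
  sc <- simulation_scenario(n = 60, p = 40, m = 10, effect = 1.5)
  d <- simulate_dataset(sc, seed = 6)
  lc1 <- learning_curve(d, single_gene_classifier(), n_splits = 5, seed = 7)
  lc2 <- learning_curve(d, single_gene_classifier(), n_splits = 5, seed = 7)
  expect_identical(lc1$mean_error, lc2$mean_error)
  broken <- split_classifier(
    fit = function(expr, labels) stop("boom"),
    predict = function(model, expr) NULL
  )
  expect_error(learning_curve(d, broken, n_splits = 2, seed = 8),
               "classifier failed at t = 10, split 1")
})

test_that("bias2_curve uses fitted values with B(n) = 0 by construction", {
  sc <- simulation_scenario(n = 80, p = 60, m = 30, effect = 1.5)
  d <- simulate_dataset(sc, seed = 9)
  lc <- learning_curve(d, single_gene_classifier(), n_splits = 20, seed = 10)
  B <- bias2_curve(lc)
  f_t <- predict(lc$fit, lc$grid)
  f_n <- predict(lc$fit, lc$n)
  expect_equal(B, (f_t - f_n)^2)
  expect_true(all(B >= 0))
  # flat fitted curve => B identically zero
  lc_flat <- lc
  lc_flat$fit$fitted_values <- rep(0.4, length(lc$fit$fitted_values))
  expect_equal(bias2_curve(lc_flat), rep(0, length(lc$grid)))
})

test_that("variance_curve behaves like an A+V estimate", {
  # near-perfect separation: accuracies are near-constant, variance near 0
  sc_easy <- simulation_scenario(n = 80, p = 50, m = 30, effect = 3.0)
  d_easy <- simulate_dataset(sc_easy, seed = 11)
  vc_easy <- variance_curve(d_easy, ccp_classifier(0.01), n_boot = 25, seed = 12)
  expect_true(all(vc_easy$av_estimate < 0.01))
  # moderate accuracy: the estimate at the largest t is at least of the
  # order of the binomial component it contains (V is a lower-bound part)
  sc_mod <- simulation_scenario(n = 80, p = 50, m = 1, effect = 1.6)
  d_mod <- simulate_dataset(sc_mod, seed = 13)
  vc_mod <- variance_curve(d_mod, single_gene_classifier(), n_boot = 60, seed = 14)
  acc_rough <- 0.75
  expect_gt(vc_mod$av_estimate[length(vc_mod$grid)],
            0.5 * binomial_variance(acc_rough, 10))
  # reproducibility under a fixed seed
  vc2 <- variance_curve(d_mod, single_gene_classifier(), n_boot = 60, seed = 14)
  expect_identical(vc_mod$av_estimate, vc2$av_estimate)
})

test_that("doubling the split count shrinks the Monte Carlo error of w", {
  sc <- simulation_scenario(n = 60, p = 40, m = 1, effect = 1.5)
  d <- simulate_dataset(sc, seed = 15)
  w_reps <- function(n_splits, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      set.seed(seed0 + r)
      t <- 30
      errs <- vapply(seq_len(n_splits), function(s) {
        tr <- optsplit:::.stratified_train_idx(d$labels, t)
        te <- setdiff(seq_len(60), tr)
        cls <- single_gene_classifier()
        mod <- cls$fit(d$expr[, tr, drop = FALSE], d$labels[tr])
        mean(cls$predict(mod, d$expr[, te, drop = FALSE]) != d$labels[te])
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  }
  sd1 <- sd(w_reps(20, 25, 1000))
  sd2 <- sd(w_reps(40, 25, 2000))
  expect_lt(sd2 / sd1, 1 / sqrt(2) * 1.6)  # ~ 1/sqrt(2) up to sampling noise
})

test_that("recommend_split assembles a valid decomposition and recommendation", {
  sc <- simulation_scenario(n = 80, p = 100, m = 30, effect = 1.5)
  d <- simulate_dataset(sc, seed = 16)
  expect_message(
    res <- recommend_split(d, ccp_classifier(0.01), n_splits = 30, n_boot = 30,
                           seed = 17),
    "recommended 1,000"
  )
  dec <- res$decomposition
  expect_identical(dec$mse, dec$A + dec$V + dec$B)
  expect_identical(dec$variance_components, "composite")
  expect_gte(res$recommendation$excess_half, 0)
  expect_gte(res$recommendation$excess_twothirds, 0)
  expect_true(res$recommendation$t_opt %in% dec$grid)
  expect_true(res$recommendation$full_data_accuracy >= 0 &&
                res$recommendation$full_data_accuracy <= 1)
})

test_that("permuted-label data pushes the recommendation toward small training sets", {
  sc <- simulation_scenario(n = 80, p = 60, m = 20, effect = 1.5)
  d <- simulate_dataset(sc, seed = 18)
  set.seed(19)
  d_null <- expression_dataset(d$expr, sample(as.character(d$labels)))
  res <- suppressMessages(
    recommend_split(d_null, single_gene_classifier(), n_splits = 60, n_boot = 60,
                    seed = 20)
  )
  # no learning: B ~ 0 and the variance term drives t_opt toward the
  # grid minimum (large test sets)
  expect_lte(res$recommendation$t_opt, 30)
  expect_lt(max(res$decomposition$B), 0.01)
})
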