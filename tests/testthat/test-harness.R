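test_that("Wilson intervals match the closed form", {
  # (0, 100): rate 0, upper ~ 0.036
  ci <- error_rate_with_ci(0, 100)
  expect_equal(ci$rate, 0)
  expect_equal(ci$upper, 0.0370, tolerance = 0.02)
  # (n, n): rate 1
  expect_equal(error_rate_with_ci(50, 50)$rate, 1)
  # (50, 100): interval symmetric about ~0.5
  ci2 <- error_rate_with_ci(50, 100)
  expect_equal(ci2$rate, 0.5)
  expect_equal(ci2$upper - 0.5, 0.5 - ci2$lower, tolerance = 1e-10)
  # (5, 100): the worked Wilson example
  ci3 <- error_rate_with_ci(5, 100)
  expect_equal(ci3$lower, 0.021, tolerance = 0.05)
  expect_equal(ci3$upper, 0.112, tolerance = 0.05)
})

test_that("a uniform-p stub recovers every alpha within Wilson coverage", {
  stub <- list(unif = function(cells) de_outcome("unif", p_value = runif(1)))
  grid <- experiment_grid(n_per_group_levels = 2, expected_cells_levels = 5,
                          n_reps = 10000, methods = stub, master_seed = 77)
  suppressWarnings(res <- run_type1_experiment(calibration_default(), grid))
  for (a in grid$alphas) {
    row <- res[res$alpha == a, ]
    expect_gte(a, row$ci_lower)
    expect_lte(a, row$ci_upper)
  }
})

test_that("denominators account for every replicate", {
  flaky <- list(fl = function(cells) {
    if (runif(1) < 0.3) failed_outcome("fl", "synthetic failure")
    else de_outcome("fl", p_value = runif(1))
  })
  grid <- experiment_grid(n_per_group_levels = 2, expected_cells_levels = 5,
                          n_reps = 500, alphas = 0.05, methods = flaky,
                          master_seed = 5)
  suppressWarnings(res <- run_type1_experiment(calibration_default(), grid))
  expect_equal(res$n_converged + res$n_failed, 500)
  expect_gt(res$n_failed, 50)
  expect_false(res$unreliable)
})

test_that("the harness is deterministic and method-order invariant", {
  p <- calibration_default()
  grid1 <- experiment_grid(n_per_group_levels = 3, expected_cells_levels = 10,
                           n_reps = 30, alphas = 0.05,
                           methods = c("hurdle_fixed", "gee1"),
                           master_seed = 9)
  grid2 <- experiment_grid(n_per_group_levels = 3, expected_cells_levels = 10,
                           n_reps = 30, alphas = 0.05,
                           methods = c("gee1", "hurdle_fixed"),
                           master_seed = 9)
  r1 <- run_type1_experiment(p, grid1)
  r2 <- run_type1_experiment(p, grid2)
  expect_equal(r1[r1$method == "gee1", "rate"],
               r2[r2$method == "gee1", "rate"])
  r1b <- run_type1_experiment(p, grid1)
  expect_identical(r1, r1b)
})

test_that("rank-order report scores perfect and random stubs correctly", {
  # perfect method: p = exp(-|log fc|), reconstructed from the returned
  # fold changes (monotone in the truth, so its rank correlation is 1)
  res <- run_rank_order_experiment(calibration_default(), n_genes = 80,
                                   n_per_group = 3, expected_cells = 10,
                                   methods = list(
                                     noise = function(cells)
                                       de_outcome("noise", p_value = runif(1))),
                                   seed = 13)
  pv <- exp(-abs(log(pmax(res$fold_changes, 1e-6))))
  rc_perfect <- -cor(pv, abs(log(pmax(res$fold_changes, 1e-6))),
                     method = "spearman")
  expect_equal(rc_perfect, 1)
  expect_lt(abs(res$rank_correlation["noise"]), 0.3)
})

test_that("sensitivity and specificity bookkeeping is exact", {
  p <- c(0.001, 0.2, 0.03, NA, 0.5, 0.01)
  isnull <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  s <- sensitivity_specificity(p, isnull, alpha = 0.05)
  expect_equal(s$sensitivity, 2 / 3)
  expect_equal(s$specificity, 1 - 1 / 2)
  # all-null truth: sensitivity undefined
  s2 <- sensitivity_specificity(c(0.1, 0.9), c(TRUE, TRUE))
  expect_true(is.na(s2$sensitivity))
  # perfect method
  s3 <- sensitivity_specificity(c(1e-9, 1e-8, 0.8), c(FALSE, FALSE, TRUE))
  expect_equal(s3$sensitivity, 1)
})
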