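test_that("calibration recovers known generative constants from simulated data", {
  # parameter-recovery oracle with negligible dropout, where the
  # non-zero-conditioned moment pipeline is close to consistent
  p <- params_with(dropout_shape = 1e-3, dropout_rate = 1e6,
                   f2_intercept = 1)
  d <- design_spec(10, "FIXED", 60)   # 20 individuals
  m <- simulate_matrix(p, d, n_genes = 220, seed = 101)
  est <- suppressWarnings(
    estimate_calibration(m, n_draws = 150, seed = 102))
  # gamma law of grand means: rate within 20%, shape more loosely (the
  # per-gene estimator noise deconvolves into the shape)
  expect_lt(abs(est$grand_mean_rate - p$grand_mean_rate) /
              p$grand_mean_rate, 0.2)
  expect_lt(abs(est$grand_mean_shape - p$grand_mean_shape) /
              p$grand_mean_shape, 0.5)
  # f1 slope within 20%
  expect_lt(abs(est$f1_slope - p$f1_slope) / p$f1_slope, 0.2)
  # f2: the zero-truncated moment estimator attenuates the dispersion
  # trend (documented limitation); require the right sign and order
  expect_gt(est$f2_slope, 0)
  expect_lt(est$f2_slope, 3 * p$f2_slope)
  fitinfo <- attr(est, "fit")
  expect_gte(fitinfo$n_genes, 10)
})

test_that("the dropout gamma is recovered when dropout is present", {
  p <- params_with(f2_intercept = 1)
  d <- design_spec(10, "FIXED", 60)
  m <- simulate_matrix(p, d, n_genes = 200, seed = 104)
  est <- suppressWarnings(
    estimate_calibration(m, n_draws = 100, seed = 105))
  est_mean <- est$dropout_shape / est$dropout_rate
  true_mean <- p$dropout_shape / p$dropout_rate
  # zero fractions = dropout plus NB zeros, so a small upward bias is
  # expected; 0.1 absolute covers it plus Monte-Carlo noise
  expect_lt(abs(est_mean - true_mean), 0.1)
})

test_that("degenerate calibration inputs raise the documented errors", {
  counts <- matrix(rpois(40, 5), nrow = 10)
  m1 <- make_mgm(counts, rep("only", 4))
  expect_error(estimate_calibration(m1), "individuals")
  # one gene duplicated everywhere: pruning leaves a single gene
  base <- rpois(30, 20)
  m2 <- make_mgm(matrix(rep(base, 50), nrow = 50, byrow = TRUE),
                 rep(letters[1:3], each = 10))
  expect_error(suppressWarnings(estimate_calibration(m2, n_draws = 20)),
               "unstable")
})

test_that("estimation conventions apply the two dispersion formulas per individual", {
  # underdispersed values (var < mean): the printed form is positive and
  # applied as written; the classical NB size diverges and is clamped
  counts_u <- matrix(rep(c(9, 10, 11), 20), nrow = 1)
  m_u <- make_mgm(counts_u, rep(c("a", "b"), each = 30))
  mom_p <- estimate_gene_moments(m_u, 1, n_draws = 20,
                                 convention = "AS_PRINTED")
  wm <- mom_p$within_sample_means[1]
  wv <- mom_p$within_sample_variances[1]
  expect_equal(unname(mom_p$dispersions[1]), unname(wm^2 / wv - wm))
  mom_c <- estimate_gene_moments(m_u, 1, n_draws = 20,
                                 convention = "CLASSICAL")
  expect_gt(unname(mom_c$dispersions[1]), 1e5)  # Poisson-like clamp

  # overdispersed NB values: the classical form recovers the size while
  # the printed form goes negative and clamps at the floor
  set.seed(103)
  counts_o <- matrix(rnbinom(200, mu = 50, size = 2), nrow = 1)
  m_o <- make_mgm(counts_o, rep(c("a", "b"), each = 100))
  mom_c2 <- estimate_gene_moments(m_o, 1, n_draws = 20,
                                  convention = "CLASSICAL")
  wm2 <- mom_c2$within_sample_means[1]
  wv2 <- mom_c2$within_sample_variances[1]
  expect_equal(unname(mom_c2$dispersions[1]), unname(wm2^2 / (wv2 - wm2)))
  mom_p2 <- estimate_gene_moments(m_o, 1, n_draws = 20,
                                  convention = "AS_PRINTED",
                                  dispersion_floor = 0.01)
  expect_equal(unname(mom_p2$dispersions[1]), 0.01)
})
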