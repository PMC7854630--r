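test_that("log transform maps zeros to zero and honours base and offset", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(1, base = 2), 1)
  expect_equal(log_transform(7, base = exp(1)), log(8))
  expect_error(log_transform(-1), "non-negative")
})

test_that("component combination equals the chi-square survival function", {
  expect_equal(combine_component_tests(0, 1, 0, 1), 1)
  # frozen from the survival-function oracle: P(chisq_2 > 7.68)
  expect_equal(combine_component_tests(3.84, 1, 3.84, 1),
               pchisq(7.68, 2, lower.tail = FALSE))
  expect_equal(combine_component_tests(3.84, 1, 3.84, 1), 0.0214936,
               tolerance = 1e-5)
  # a missing component degrades to the one-df test
  x <- 5.3
  expect_equal(combine_component_tests(x, 1, NA, NA),
               pchisq(x, 1, lower.tail = FALSE))
  expect_true(is.na(combine_component_tests(0, 0, NA, NA)))
})

test_that("no-signal input gives p near 1 using the continuous df only", {
  cells <- make_cells(rep(5L, 40), rep(1:8, each = 5), rep(0:1, each = 20))
  out <- hurdle_fixed_test(cells)
  # all z = 1: discrete part degenerate; constant y: zero group effect
  expect_true(is.na(out$components$df_discrete) ||
                out$components$df_discrete == 0)
  expect_true(out$converged)
  expect_equal(out$components$df_continuous, 1)
  expect_gt(out$p_value, 0.99)
})

test_that("fixed hurdle matches an independently fitted two-component GLM", {
  set.seed(11)
  n <- 400
  g <- rep(0:1, each = n / 2)
  ind <- rep(1:8, each = n / 8)
  z <- rbinom(n, 1, plogis(-0.3 + 0.8 * g))
  raw <- ifelse(z == 1, pmax(1, rpois(n, exp(2 + 1 * g))), 0L)
  cells <- make_cells(raw, ind, g)
  out <- hurdle_fixed_test(cells)

  # oracle: standard glm/lm LRTs computed independently
  y <- log2(raw + 1)
  f1 <- glm(z ~ g, family = binomial())
  f0 <- glm(z ~ 1, family = binomial())
  cd <- f0$deviance - f1$deviance
  pos <- z == 1
  rss1 <- sum(resid(lm(y[pos] ~ g[pos]))^2)
  rss0 <- sum(resid(lm(y[pos] ~ 1))^2)
  cc <- sum(pos) * log(rss0 / rss1)
  p_oracle <- pchisq(cd + cc, 2, lower.tail = FALSE)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-8)

  # strong continuous shift is detected decisively
  raw2 <- ifelse(z == 1, pmax(1, rpois(n, exp(2 + 5 * g))), 0L)
  out2 <- hurdle_fixed_test(make_cells(raw2, ind, g))
  expect_lt(out2$p_value, 1e-6)
})

test_that("separation and all-zero inputs are flagged as failures", {
  g <- rep(0:1, each = 10)
  # group 0 entirely zero, group 1 mixed: separation
  raw <- c(rep(0L, 10), c(0L, 3L, 4L, 0L, 2L, 5L, 1L, 0L, 2L, 3L))
  out <- hurdle_fixed_test(make_cells(raw, rep(1:4, each = 5), g))
  expect_false(out$converged)
  expect_match(out$failure_reason, "separation")
  out2 <- hurdle_fixed_test(make_cells(rep(0L, 20), rep(1:4, each = 5), g))
  expect_false(out2$converged)
})

test_that("logistic GLMM collapses to plain logistic at the boundary", {
  # identical proportions of ones per individual: sigma_gamma^2 -> 0
  z <- rep(c(1, 1, 0, 0), 8)
  g <- rep(0:1, each = 16)
  ind <- factor(rep(1:8, each = 4))
  fit <- fit_logistic_random_intercept(z, g, ind, quadrature_points = 5)
  expect_true(fit$converged)
  expect_lt(fit$re_variance, 1e-4)
  ref <- glm(z ~ g, family = binomial())
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-3)
})

test_that("adaptive quadrature matches brute-force integration on a toy", {
  # 3 individuals x 4 cells; marginal likelihood by dense numeric
  # integration over the random intercept at the fitted parameters
  z <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 1, 0)
  g <- rep(c(0, 1, 0), each = 4)
  ind <- factor(rep(1:3, each = 4))
  fit <- fit_logistic_random_intercept(z, g, ind, quadrature_points = 25)
  expect_true(fit$converged)
  beta <- fit$beta; s2 <- max(fit$re_variance, 1e-12)
  grid <- seq(-8, 8, length.out = 20001) * sqrt(s2)
  if (s2 < 1e-10) grid <- 0
  ll <- 0
  for (j in levels(ind)) {
    i <- ind == j
    eta <- beta[1] + beta[2] * g[i]
    contrib <- vapply(grid, function(u) {
      pr <- plogis(eta + u)
      prod(ifelse(z[i] == 1, pr, 1 - pr))
    }, 0)
    dens <- if (length(grid) > 1) dnorm(grid, 0, sqrt(s2)) else 1
    int <- if (length(grid) > 1)
      sum(contrib * dens) * (grid[2] - grid[1]) else contrib
    ll <- ll + log(int)
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("logistic GLMM recovers a known random-intercept variance", {
  set.seed(21)
  n_ind <- 200; m <- 50
  u <- rnorm(n_ind, 0, 1)  # sigma^2 = 1
  g <- rep(rep(0:1, each = n_ind / 2), each = m)
  ind <- rep(seq_len(n_ind), each = m)
  z <- rbinom(n_ind * m, 1, plogis(0.2 + 0.5 * g + u[ind]))
  fit <- fit_logistic_random_intercept(z, g, factor(ind))
  expect_true(fit$converged)
  expect_lt(abs(fit$re_variance - 1), 0.25)
})

test_that("linear mixed component recovers variance components and edge cases", {
  set.seed(22)
  n_ind <- 100; m <- 20
  u <- rnorm(n_ind, 0, sqrt(2))
  g <- rep(rep(0:1, each = n_ind / 2), each = m)
  ind <- rep(seq_len(n_ind), each = m)
  y <- 1 + 0.3 * g + u[ind] + rnorm(n_ind * m, 0, 1)
  fit <- fit_linear_random_intercept(y, g, factor(ind))
  expect_true(fit$converged)
  expect_lt(abs(fit$re_variance - 2) / 2, 0.2)
  expect_lt(abs(fit$resid_variance - 1), 0.2)

  # zero between-individual spread: sigma_gamma^2 ~ 0 and beta = OLS
  set.seed(23)
  y2 <- 2 + 0.5 * g + rnorm(n_ind * m, 0, 1)
  fit2 <- fit_linear_random_intercept(y2, g, factor(ind))
  expect_lt(fit2$re_variance, 0.01)
  expect_equal(fit2$beta, unname(coef(lm(y2 ~ g))), tolerance = 1e-3)

  # two individuals total (one per group): wide CI but no crash
  y3 <- rnorm(40); g3 <- rep(0:1, each = 20); i3 <- factor(rep(1:2, each = 20))
  fit3 <- fit_linear_random_intercept(y3, g3, i3)
  expect_true(fit3$converged)
  expect_equal(fit3$df, 1)
})

test_that("mixed hurdle reproduces the fixed hurdle when the hierarchy is absent", {
  # balanced data with identical individuals: RE variances hit the
  # boundary and the mixed statistics coincide with the fixed ones
  raw <- rep(c(0L, 2L, 3L, 0L, 5L, 1L), 8)
  g <- rep(0:1, each = 24)
  ind <- rep(1:8, each = 6)
  cells <- make_cells(raw, ind, g)
  fx <- hurdle_fixed_test(cells)
  mx <- hurdle_mixed_test(cells, quadrature_points = 5)
  expect_true(mx$converged)
  expect_equal(mx$statistic, fx$statistic, tolerance = 1e-4)
  expect_equal(mx$p_value, fx$p_value, tolerance = 1e-4)
})

test_that("signal confined to the positive part leaves the discrete chi-square at zero", {
  set.seed(24)
  g <- rep(0:1, each = 40)
  ind <- rep(1:8, each = 10)
  z <- rep(rep(c(1, 1, 1, 0, 1), 2), 8)  # identical zero pattern per group
  raw <- ifelse(z == 1, rpois(80, exp(1.5 + 1.2 * g)) + 1L, 0L)
  out <- hurdle_mixed_test(make_cells(raw, ind, g))
  expect_true(out$converged)
  expect_lt(out$components$chisq_discrete, 1e-4)
  expect_gt(out$components$chisq_continuous, out$components$chisq_discrete)
})
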