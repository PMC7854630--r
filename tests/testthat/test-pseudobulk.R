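test_that("aggregation computes per-individual means and sums exactly", {
  cells <- make_cells(c(2L, 4L), c("a", "a"), c(0, 0))
  agg_m <- pseudobulk_aggregate(cells, "MEAN")
  agg_s <- pseudobulk_aggregate(cells, "SUM")
  expect_equal(agg_m$value, 3)
  expect_equal(agg_s$value, 6)
  # single cell: mean = sum = value
  c1 <- make_cells(5L, "x", 0)
  expect_equal(pseudobulk_aggregate(c1, "MEAN")$value,
               pseudobulk_aggregate(c1, "SUM")$value)
})

test_that("sum equals mean times cell count for arbitrary inputs", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    raw <- rpois(n, 10)
    ind <- sample(letters[1:5], n, replace = TRUE)
    cells <- make_cells(raw, ind, as.integer(ind %in% letters[1:2]))
    m <- pseudobulk_aggregate(cells, "MEAN")
    s <- pseudobulk_aggregate(cells, "SUM")
    expect_equal(s$value, m$value * m$n_cells)
    expect_equal(s$n_cells, m$n_cells)
  }
})

test_that("aggregation and the NB test are invariant to cell order", {
  set.seed(32)
  raw <- rpois(60, 20)
  ind <- rep(1:6, each = 10)
  g <- rep(0:1, each = 30)
  cells <- make_cells(raw, ind, g)
  perm <- sample(60)
  cells_p <- make_cells(raw[perm], ind[perm], g[perm])
  expect_equal(pseudobulk_aggregate(cells, "SUM"),
               pseudobulk_aggregate(cells_p, "SUM"))
  expect_equal(nb_wald_test(pseudobulk_aggregate(cells, "SUM"))$p_value,
               nb_wald_test(pseudobulk_aggregate(cells_p, "SUM"))$p_value)
})

test_that("identical aggregate vectors give a null Wald statistic", {
  samples <- data.frame(individual = letters[1:8],
                        group = rep(0:1, each = 4),
                        value = rep(c(10, 12, 14, 16), 2),
                        n_cells = 1L)
  out <- nb_wald_test(samples)
  expect_true(out$converged)
  expect_lt(abs(out$statistic), 1e-6)
  expect_gt(out$p_value, 0.999)
})

test_that("NB Wald recovers a known ratio on Poisson aggregates", {
  set.seed(33)
  n <- 20
  mu0 <- 60
  hits <- 0
  for (r in 1:10) {
    y <- c(rpois(n, mu0), rpois(n, 2 * mu0))
    samples <- data.frame(individual = seq_len(2 * n),
                          group = rep(0:1, each = n), value = y,
                          n_cells = 1L)
    out <- nb_wald_test(samples)
    # oracle: standard Poisson GLM on the same data
    oracle <- glm(y ~ rep(0:1, each = n), family = poisson())
    se <- summary(oracle)$coefficients[2, 2]
    if (abs(out$effect_estimate - log(2)) < 3 * se) hits <- hits + 1
    expect_equal(out$effect_estimate, unname(coef(oracle)[2]),
                 tolerance = 0.02)
  }
  expect_gte(hits, 9)
})

test_that("mean rounding happens only at the NB boundary and is flagged", {
  cells <- make_cells(c(1L, 2L, 4L, 9L, 3L, 7L, 2L, 8L),
                      rep(1:4, each = 2), rep(0:1, each = 4))
  agg <- pseudobulk_aggregate(cells, "MEAN")
  expect_equal(agg$value, c(1.5, 6.5, 5, 5))  # full precision retained
  out <- nb_wald_test(agg)
  expect_true(out$components$rounded)
  outs <- nb_wald_test(pseudobulk_aggregate(cells, "SUM"))
  expect_false(outs$components$rounded)
})

test_that("degenerate pseudo-bulk inputs fail explicitly", {
  s1 <- data.frame(individual = 1:3, group = c(0, 0, 1),
                   value = c(5, 6, 7), n_cells = 1L)
  expect_false(nb_wald_test(s1)$converged)  # 1 sample in a group
  s2 <- data.frame(individual = 1:8, group = rep(0:1, each = 4),
                   value = c(rep(0, 4), 5:8), n_cells = 1L)
  expect_false(nb_wald_test(s2)$converged)  # all-zero group
})

test_that("mean and sum tests agree on balanced designs", {
  set.seed(34)
  raw <- rpois(80, 30)
  ind <- rep(1:8, each = 10)
  g <- rep(0:1, each = 40)
  cells <- make_cells(raw, ind, g)
  om <- pseudobulk_test(cells, "MEAN")
  os <- pseudobulk_test(cells, "SUM")
  expect_equal(om$effect_estimate, os$effect_estimate, tolerance = 0.05)
  expect_true(om$converged && os$converged)
})
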