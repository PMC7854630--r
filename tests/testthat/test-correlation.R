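test_that("zero-mean genes are dropped, order preserved", {
  counts <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(0, 4), g3 = c(0, 0, 1, 0))
  m <- make_mgm(counts, c("a", "a", "b", "b"))
  f <- filter_expressed_genes(m)
  expect_equal(f$gene_ids, c("g1", "g3"))
  # identity when nothing is zero-mean
  m2 <- make_mgm(counts[c(1, 3), , drop = FALSE], c("a", "a", "b", "b"))
  expect_equal(dim(filter_expressed_genes(m2)), dim(m2))
})

test_that("pruning keeps one copy of duplicated genes and is deterministic", {
  set.seed(71)
  base <- rpois(40, 5)
  counts <- rbind(matrix(rep(base, 10), nrow = 10, byrow = TRUE),
                  matrix(rpois(5 * 40, 5), nrow = 5))
  m <- make_mgm(counts, rep(letters[1:4], each = 10))
  kept <- prune_correlated_genes(m, seed = 1)
  dup_kept <- sum(kept %in% paste0("gene", 1:10))
  expect_equal(dup_kept, 1)
  expect_identical(prune_correlated_genes(m, seed = 5),
                   prune_correlated_genes(m, seed = 5))
  expect_error(prune_correlated_genes(make_mgm(
    matrix(0, 0, 4), rep("a", 4))), "empty")
})

test_that("independent genes survive pruning up to the cap", {
  set.seed(72)
  counts <- matrix(runif(600 * 200), nrow = 600)
  m <- make_mgm(counts, rep(letters[1:10], each = 20))
  kept <- prune_correlated_genes(m, threshold = 0.25, max_genes = 500,
                                 seed = 2)
  expect_equal(length(kept), 500)
})

test_that("cell-pair Spearman correlations hit exact endpoints", {
  # two identical cells: rho = 1; rank-reversed profiles: rho = -1
  prof <- c(5, 1, 4, 2, 3)
  counts <- cbind(prof, prof, 6 - prof)  # third profile rank-reversed
  rownames(counts) <- paste0("g", 1:5)
  m <- make_mgm(counts, c("a", "a", "a"))
  intra <- intra_individual_correlations(m, paste0("g", 1:5))
  expect_equal(sort(intra$a), c(-1, -1, 1))
})

test_that("pair counts follow the choose(n, 2) combinatorial oracle", {
  set.seed(73)
  for (n in c(2, 5, 10)) {
    counts <- matrix(rpois(30 * n, 10), nrow = 30)
    m <- make_mgm(counts, rep("solo", n))
    intra <- intra_individual_correlations(m, paste0("gene", 1:30))
    expect_equal(length(intra$solo), choose(n, 2))
  }
})

test_that("inter-individual draws produce one pair per draw for two individuals", {
  set.seed(74)
  counts <- matrix(rpois(20 * 8, 10), nrow = 20)
  m <- make_mgm(counts, rep(c("a", "b"), each = 4))
  inter <- inter_individual_correlations(m, paste0("gene", 1:20),
                                         n_draws = 50, seed = 3)
  expect_equal(length(inter), 50)
  expect_true(all(lengths(inter) == 1))
  i2 <- inter_individual_correlations(m, paste0("gene", 1:20),
                                      n_draws = 50, seed = 3)
  expect_identical(inter, i2)
})

test_that("Spearman is invariant to strictly monotone per-cell transforms", {
  set.seed(75)
  counts <- matrix(rpois(40 * 6, 20), nrow = 40)
  m1 <- make_mgm(counts, rep(c("a", "b"), each = 3))
  m2 <- make_mgm(counts^2 + 3, rep(c("a", "b"), each = 3))  # monotone
  genes <- paste0("gene", 1:40)
  expect_equal(intra_individual_correlations(m1, genes)$a,
               intra_individual_correlations(m2, genes)$a)
})

test_that("hierarchical data separate intra from inter correlation; iid data do not", {
  p <- calibration_default()
  d <- design_spec(5, "POISSON", 25)
  m <- simulate_matrix(p, d, n_genes = 120, seed = 80)
  cs <- correlation_diagnostic(m, n_draws = 150, seed = 81)
  expect_gt(cs$median_intra, cs$median_inter)

  m0 <- simulate_matrix(iid_params(), d, n_genes = 120, seed = 82)
  cs0 <- correlation_diagnostic(m0, n_draws = 150, seed = 83)
  expect_lt(abs(cs0$median_intra - cs0$median_inter), 0.05)
})

test_that("cross-cell-type diagnostics balance and reduce correctly", {
  set.seed(76)
  n_ind <- 4; per <- 24
  counts <- matrix(rpois(30 * n_ind * per, 10), nrow = 30)
  ind <- rep(letters[1:n_ind], each = per)
  ct <- rep(rep(c("alpha", "beta", "ductal"), each = per / 3), n_ind)
  m <- make_mgm(counts, ind, cell_type = ct)
  cs <- cross_celltype_correlations(m, paste0("gene", 1:30),
                                    n_per_type = 5, n_draws = 20, seed = 4)
  expect_s3_class(cs, "correlation_summary")
  expect_length(attr(cs, "excluded_individuals"), 0)
  # an individual lacking enough cells of one type is excluded
  ct2 <- ct; ct2[ind == "a" & ct == "alpha"][1:6] <- "beta"
  m2 <- make_mgm(counts, ind, cell_type = ct2)
  cs2 <- cross_celltype_correlations(m2, paste0("gene", 1:30),
                                     n_per_type = 8, n_draws = 10, seed = 5)
  expect_true("a" %in% attr(cs2, "excluded_individuals"))
})
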