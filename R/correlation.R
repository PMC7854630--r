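# Intra- vs inter-individual correlation diagnostics: Spearman correlation
# between the expression profiles of cell pairs, on a pruned set of
# mutually weakly-correlated genes, compared within and across individuals.

#' Drop genes whose mean expression is zero
#'
#' @param matrix A [multigene_matrix()].
#' @return The matrix restricted to genes with positive mean, order
#'   preserved.
#' @export
filter_expressed_genes <- function(matrix) {
  stopifnot(inherits(matrix, "multigene_matrix"))
  keep <- rowMeans(matrix$counts) > 0
  subset_matrix(matrix, genes = which(keep))
}

#' Greedy pruning to a set of weakly correlated genes
#'
#' Repeatedly samples one remaining gene uniformly, keeps it, and removes
#' every other remaining gene whose Spearman correlation with it (across
#' cells) exceeds the threshold; stops when \code{max_genes} genes are
#' kept or the pool is exhausted. The guarantee is against the sampled
#' gene that removed them, not pairwise among all kept genes — the greedy
#' procedure as defined.
#'
#' @param matrix A [multigene_matrix()].
#' @param threshold Spearman correlation above which a gene is trimmed
#'   (default 0.25).
#' @param max_genes Maximum genes kept (default 500).
#' @param seed Optional seed; fixed seed gives an identical subset.
#' @return Character vector of kept gene ids.
#' @export
prune_correlated_genes <- function(matrix, threshold = 0.25,
                                   max_genes = 500, seed = NULL) {
  stopifnot(inherits(matrix, "multigene_matrix"))
  if (nrow(matrix$counts) == 0) stop("empty matrix")
  if (!is.null(seed)) set.seed(seed)
  # rank each gene across cells once; Spearman = Pearson on ranks
  ranks <- t(apply(matrix$counts, 1, rank))
  rc <- ranks - rowMeans(ranks)
  rs <- sqrt(rowSums(rc^2))
  remaining <- seq_len(nrow(rc))
  kept <- integer(0)
  while (length(remaining) > 0 && length(kept) < max_genes) {
    pick <- remaining[sample.int(length(remaining), 1L)]
    kept <- c(kept, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    if (rs[pick] == 0) next  # constant gene correlates with nothing
    rho <- as.numeric(rc[remaining, , drop = FALSE] %*% rc[pick, ]) /
      (rs[remaining] * rs[pick])
    rho[!is.finite(rho)] <- 0
    remaining <- remaining[rho <= threshold]
  }
  matrix$gene_ids[sort(kept)]
}

# Spearman correlation matrix between cells over a gene subset. Cells
# whose profile is constant across the subset get NA columns (no defined
# ranks); callers skip and count those pairs.
cell_correlation_matrix <- function(matrix, genes) {
  counts <- matrix$counts[genes, , drop = FALSE]
  ranks <- apply(counts, 2, rank)
  sds <- apply(ranks, 2, stats::sd)
  ranks[, sds == 0] <- NA
  suppressWarnings(stats::cor(ranks))
}

#' Within-individual cell-pair Spearman correlations
#'
#' For each individual with at least two cells, the Spearman correlation
#' of every pair of its cells' expression profiles across the gene
#' subset.
#'
#' @param matrix A [multigene_matrix()].
#' @param genes Character vector of gene ids (e.g. from
#'   [prune_correlated_genes()]).
#' @return Named list, one numeric vector of C(n, 2) correlations per
#'   individual; individuals with one cell are skipped (attribute
#'   \code{skipped_individuals}); pairs with a constant profile are
#'   dropped (attribute \code{n_undefined_pairs}).
#' @export
intra_individual_correlations <- function(matrix, genes) {
  cmat <- cell_correlation_matrix(matrix, genes)
  ind <- matrix$cell_metadata$individual_id
  out <- list()
  skipped <- character(0)
  n_undef <- 0L
  for (lev in unique(ind)) {
    cells <- which(ind == lev)
    if (length(cells) < 2) { skipped <- c(skipped, lev); next }
    vals <- cmat[cells, cells][upper.tri(diag(length(cells)))]
    n_undef <- n_undef + sum(is.na(vals))
    out[[lev]] <- vals[!is.na(vals)]
  }
  structure(out, skipped_individuals = skipped,
            n_undefined_pairs = n_undef)
}

#' Across-individual cell-pair Spearman correlations
#'
#' Per draw, one cell is sampled from each individual and all pairwise
#' Spearman correlations among the drawn cells are recorded.
#'
#' @inheritParams intra_individual_correlations
#' @param n_draws Number of one-cell-per-individual draws (default 1000).
#' @param seed Optional seed.
#' @return List of numeric vectors, one per draw.
#' @export
inter_individual_correlations <- function(matrix, genes, n_draws = 1000,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- matrix$cell_metadata$individual_id
  levs <- unique(ind)
  if (length(levs) < 2) stop("need >= 2 individuals")
  cmat <- cell_correlation_matrix(matrix, genes)
  by_ind <- split(seq_along(ind), factor(ind, levels = levs))
  lapply(seq_len(n_draws), function(d) {
    cells <- vapply(by_ind, function(v) v[sample.int(length(v), 1L)], 0L)
    vals <- cmat[cells, cells][upper.tri(diag(length(cells)))]
    vals[!is.na(vals)]
  })
}

#' Summarize intra- vs inter-individual correlations
#'
#' @param intra Result of [intra_individual_correlations()].
#' @param inter Result of [inter_individual_correlations()].
#' @param n_genes_used Number of genes in the subset used.
#' @return An object of class \code{"correlation_summary"} with the pooled
#'   correlation vectors, their medians and interquartile ranges.
#' @export
correlation_summary <- function(intra, inter, n_genes_used = NA_integer_) {
  iv <- unlist(intra, use.names = FALSE)
  ev <- unlist(inter, use.names = FALSE)
  structure(list(intra = intra, inter = inter,
                 median_intra = stats::median(iv),
                 median_inter = stats::median(ev),
                 iqr_intra = stats::IQR(iv), iqr_inter = stats::IQR(ev),
                 n_genes_used = n_genes_used,
                 n_draws = length(inter)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "correlation_summary (%s genes): median intra %.3f (IQR %.3f), median inter %.3f (IQR %.3f)\n",
    x$n_genes_used, x$median_intra, x$iqr_intra,
    x$median_inter, x$iqr_inter))
  invisible(x)
}

#' Intra-/inter-individual correlations across cell types
#'
#' Intra: repeated draws of one cell per cell type within an individual,
#' all pairwise correlations among the drawn cells. Inter: the data are
#' reduced to a balanced subset of \code{n_per_type} cells per cell type
#' per individual, and one cell per individual is drawn per draw for the
#' across-individual pairs. Individuals lacking a cell type (intra) or
#' lacking \code{n_per_type} cells of every type (inter) are skipped.
#'
#' @inheritParams intra_individual_correlations
#' @param n_per_type Cells of each type retained per individual for the
#'   balanced inter comparison (default 10).
#' @param n_draws Number of draws for both scopes (default 1000).
#' @param seed Optional seed.
#' @return A [correlation_summary()]; attribute
#'   \code{excluded_individuals} lists individuals without enough cells
#'   for the balanced subset.
#' @export
cross_celltype_correlations <- function(matrix, genes, n_per_type = 10,
                                        n_draws = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- matrix$cell_metadata
  if (is.null(md$cell_type)) stop("cell_type metadata required")
  cmat <- cell_correlation_matrix(matrix, genes)
  types <- unique(md$cell_type)
  inds <- unique(md$individual_id)

  intra <- list()
  for (lev in inds) {
    draws <- c()
    for (d in seq_len(n_draws)) {
      cells <- integer(0)
      for (ty in types) {
        pool <- which(md$individual_id == lev & md$cell_type == ty)
        if (length(pool)) cells <- c(cells, pool[sample.int(length(pool), 1L)])
      }
      if (length(cells) >= 2) {
        vals <- cmat[cells, cells][upper.tri(diag(length(cells)))]
        draws <- c(draws, vals[!is.na(vals)])
      }
    }
    if (length(draws)) intra[[lev]] <- draws
  }

  # balanced subset for the across-individual comparison
  excluded <- character(0)
  balanced <- integer(0)
  bal_ind <- character(0)
  for (lev in inds) {
    picks <- integer(0)
    ok <- TRUE
    for (ty in types) {
      pool <- which(md$individual_id == lev & md$cell_type == ty)
      if (length(pool) < n_per_type) { ok <- FALSE; break }
      picks <- c(picks, sample(pool, n_per_type))
    }
    if (!ok) { excluded <- c(excluded, lev); next }
    balanced <- c(balanced, picks)
    bal_ind <- c(bal_ind, rep(lev, length(picks)))
  }
  inter <- list()
  if (length(unique(bal_ind)) >= 2) {
    by_ind <- split(balanced, bal_ind)
    inter <- lapply(seq_len(n_draws), function(d) {
      cells <- vapply(by_ind, function(v) v[sample.int(length(v), 1L)], 0L)
      vals <- cmat[cells, cells][upper.tri(diag(length(cells)))]
      vals[!is.na(vals)]
    })
  }
  out <- correlation_summary(intra, inter, n_genes_used = length(genes))
  attr(out, "excluded_individuals") <- excluded
  out
}

#' Full Fig-1-style correlation diagnostic
#'
#' Filters zero-mean genes, prunes to a weakly correlated gene subset,
#' and computes intra- and inter-individual cell-pair Spearman
#' correlations.
#'
#' @param matrix A [multigene_matrix()].
#' @param threshold,max_genes Passed to [prune_correlated_genes()].
#' @param n_draws Passed to [inter_individual_correlations()].
#' @param seed Optional seed covering pruning and draws.
#' @return A [correlation_summary()].
#' @export
correlation_diagnostic <- function(matrix, threshold = 0.25, max_genes = 500,
                                   n_draws = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- filter_expressed_genes(matrix)
  genes <- prune_correlated_genes(m, threshold, max_genes)
  intra <- intra_individual_correlations(m, genes)
  inter <- inter_individual_correlations(m, genes, n_draws)
  correlation_summary(intra, inter, n_genes_used = length(genes))
}
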