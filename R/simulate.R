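# Hierarchical generative model: gene-level grand mean from a gamma law,
# per-individual means by adding a normal offset with variance f1(group
# mean), NB counts per cell with size f2(mean), and gamma-distributed
# dropout applied as Bernoulli thinning identically across groups.

# Draw a dropout probability: gamma truncated to [0, 1] by rejection, with
# a clamp fallback if the law puts almost all mass above 1.
draw_dropout <- function(shape, rate) {
  for (i in 1:50) {
    p <- stats::rgamma(1, shape = shape, rate = rate)
    if (p <= 1) return(p)
  }
  1
}

#' Simulate one gene under the hierarchical model
#'
#' Draws a grand mean from the calibrated gamma law, forms the two group
#' means (one multiplied by the fold change), adds an independent normal
#' offset with variance \code{f1(group mean)} to obtain each individual's
#' mean, draws per-cell negative-binomial counts with size
#' \code{f2} evaluated at the grand mean (default) or the individual mean,
#' and zeroes each cell independently with the gene's dropout probability
#' (constant across groups and individuals).
#'
#' @param params A [calibration_params()] object.
#' @param design A [design_spec()] object.
#' @param dispersion_on \code{"grand"} (default): NB size from the grand /
#'   group mean; \code{"individual"}: from each individual's mean.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class \code{"single_gene_dataset"}: list with
#'   \code{values} (integer counts per cell), \code{individual_ids},
#'   \code{group_labels} (0/1, constant within individual), and
#'   \code{truth} (grand mean, group means, individual means, dispersions,
#'   dropout probability, fold change, spiked group).
#' @export
simulate_gene <- function(params, design, dispersion_on = c("grand", "individual"),
                          seed = NULL) {
  stopifnot(inherits(params, "calibration_params"),
            inherits(design, "design_spec"))
  dispersion_on <- match.arg(dispersion_on)
  if (!is.null(seed)) set.seed(seed)

  n_ind <- 2L * design$n_per_group
  group <- rep(0:1, each = design$n_per_group)

  mu_i <- stats::rgamma(1, shape = params$grand_mean_shape,
                        rate = params$grand_mean_rate)
  mu_i <- max(mu_i, params$mean_floor)
  spiked <- if (design$random_direction) stats::rbinom(1, 1, 0.5) else 1L
  group_means <- c(mu_i, mu_i)
  group_means[spiked + 1L] <- mu_i * design$fold_change
  group_means <- pmax(group_means, params$mean_floor)

  gm_j <- group_means[group + 1L]
  delta <- stats::rnorm(n_ind, 0, sqrt(eval_f1(params, gm_j)))
  mu_ij <- pmax(gm_j + delta, params$mean_floor)

  size_j <- switch(dispersion_on,
                   grand = eval_f2(params, gm_j),
                   individual = eval_f2(params, mu_ij))

  n_cells <- draw_cell_counts(design, n_ind)
  p_drop <- draw_dropout(params$dropout_shape, params$dropout_rate)

  values <- integer(sum(n_cells))
  ind_ids <- character(sum(n_cells))
  grp <- integer(sum(n_cells))
  pos <- 0L
  for (j in seq_len(n_ind)) {
    idx <- pos + seq_len(n_cells[j])
    y <- stats::rnbinom(n_cells[j], mu = mu_ij[j], size = size_j[j])
    keep <- stats::rbinom(n_cells[j], 1L, 1 - p_drop)
    values[idx] <- y * keep
    ind_ids[idx] <- sprintf("ind%02d", j)
    grp[idx] <- group[j]
    pos <- pos + n_cells[j]
  }

  structure(list(
    values = values,
    individual_ids = ind_ids,
    group_labels = grp,
    truth = list(grand_mean = mu_i,
                 group_means = group_means,
                 individual_means = mu_ij,
                 dispersions = size_j,
                 dropout_p = p_drop,
                 fold_change = design$fold_change,
                 spiked_group = spiked,
                 cells_per_individual = as.integer(n_cells))),
    class = "single_gene_dataset")
}

#' @export
print.single_gene_dataset <- function(x, ...) {
  cat(sprintf(
    "single_gene_dataset: %d cells, %d individuals, fold change %g, %.1f%% zeros\n",
    length(x$values), length(unique(x$individual_ids)),
    x$truth$fold_change, 100 * mean(x$values == 0)))
  invisible(x)
}

#' Simulate a genes-by-cells matrix under the hierarchical model
#'
#' One cell layout (individuals, groups, cells per individual) is drawn
#' once and shared by all genes; each gene is then simulated independently
#' given that layout, matching the gene-independence of the generative
#' model while giving multi-gene consumers (correlation diagnostics,
#' calibration round trips) a coherent matrix.
#'
#' @inheritParams simulate_gene
#' @param n_genes Number of genes (rows).
#' @param fold_changes Optional per-gene fold-change vector overriding
#'   \code{design$fold_change} (recycled if length 1).
#' @return A [multigene_matrix()] whose \code{cell_metadata} carries
#'   \code{individual_id} and \code{group}, with a \code{truth} attribute:
#'   data frame of per-gene grand means, fold changes and dropout
#'   probabilities.
#' @export
simulate_matrix <- function(params, design, n_genes,
                            dispersion_on = c("grand", "individual"),
                            fold_changes = NULL, seed = NULL) {
  stopifnot(n_genes >= 1)
  dispersion_on <- match.arg(dispersion_on)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fold_changes)) fold_changes <- design$fold_change
  fold_changes <- rep_len(fold_changes, n_genes)

  n_ind <- 2L * design$n_per_group
  group <- rep(0:1, each = design$n_per_group)
  n_cells <- draw_cell_counts(design, n_ind)
  ind_ids <- rep(sprintf("ind%02d", seq_len(n_ind)), times = n_cells)
  grp <- rep(group, times = n_cells)

  counts <- matrix(0L, nrow = n_genes, ncol = sum(n_cells))
  truth <- data.frame(gene = paste0("gene", seq_len(n_genes)),
                      grand_mean = NA_real_, fold_change = fold_changes,
                      dropout_p = NA_real_, spiked_group = NA_integer_)
  gm_j <- numeric(n_ind)
  for (g in seq_len(n_genes)) {
    mu_i <- max(stats::rgamma(1, params$grand_mean_shape,
                              rate = params$grand_mean_rate),
                params$mean_floor)
    spiked <- if (design$random_direction) stats::rbinom(1, 1, 0.5) else 1L
    group_means <- c(mu_i, mu_i)
    group_means[spiked + 1L] <- mu_i * fold_changes[g]
    group_means <- pmax(group_means, params$mean_floor)
    gm_j <- group_means[group + 1L]
    mu_ij <- pmax(gm_j + stats::rnorm(n_ind, 0, sqrt(eval_f1(params, gm_j))),
                  params$mean_floor)
    size_j <- switch(dispersion_on,
                     grand = eval_f2(params, gm_j),
                     individual = eval_f2(params, mu_ij))
    p_drop <- draw_dropout(params$dropout_shape, params$dropout_rate)
    y <- stats::rnbinom(sum(n_cells), mu = rep(mu_ij, times = n_cells),
                        size = rep(size_j, times = n_cells))
    y <- y * stats::rbinom(sum(n_cells), 1L, 1 - p_drop)
    counts[g, ] <- y
    truth$grand_mean[g] <- mu_i
    truth$dropout_p[g] <- p_drop
    truth$spiked_group[g] <- spiked
  }

  md <- data.frame(cell_id = sprintf("cell%05d", seq_len(sum(n_cells))),
                   individual_id = ind_ids, group = grp,
                   stringsAsFactors = FALSE)
  out <- multigene_matrix(counts, md, gene_ids = truth$gene)
  attr(out, "truth") <- truth
  out
}

#' Convert a single simulated gene to cell-level observations for testing
#'
#' Packages the raw counts with the log-transformed values, the expression
#' indicator and the design labels in the layout all differential
#' expression tests consume.
#'
#' @param dataset A [simulate_gene()] result, or a list with elements
#'   \code{values}, \code{individual_ids}, \code{group_labels}.
#' @param base,offset Passed to [log_transform()].
#' @return An object of class \code{"cell_obs"}: list with \code{raw},
#'   \code{y} (log scale), \code{z} (0/1 expression indicator),
#'   \code{group} (0/1), \code{individual} (factor).
#' @export
cell_observations <- function(dataset, base = 2, offset = 1) {
  raw <- dataset$values
  structure(list(raw = raw,
                 y = log_transform(raw, base = base, offset = offset),
                 z = as.integer(raw > 0),
                 group = dataset$group_labels,
                 individual = factor(dataset$individual_ids)),
            class = "cell_obs")
}
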