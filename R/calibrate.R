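#' Estimate calibration parameters from a reference expression matrix
#'
#' Reproduces the calibration pipeline: zero-mean genes are removed, the
#' gene set is pruned to weakly correlated genes
#' ([prune_correlated_genes()]), per-gene hierarchical moments are
#' computed ([estimate_gene_moments()]), and the generative constants are
#' fitted — a gamma law to the grand means (maximum likelihood), the
#' linear inter-individual variance function \code{f1} by least squares of
#' inter-individual variance on grand mean, the logarithmic dispersion
#' function \code{f2} by least squares of per-individual dispersion on log
#' mean, and a gamma law to the per-gene zero fractions (maximum
#' likelihood).
#'
#' @param matrix A [multigene_matrix()] with >= 2 individuals.
#' @param corr_threshold Pruning threshold (default 0.25).
#' @param max_genes Maximum genes kept by pruning (default 500).
#' @param n_draws One-cell-per-individual draws per gene for the grand
#'   mean (default 1000).
#' @param seed Optional seed (pruning and grand-mean draws).
#' @param convention Dispersion convention for [dispersion_from_moments()];
#'   \code{"CLASSICAL"} (default) yields the NB size the sampler consumes.
#' @param dispersion_floor,mean_floor Clamps stored in the result.
#' @param zero_fraction_cap Genes whose zero fraction exceeds this cap are
#'   excluded from the f1/f2 moment regressions (default 0.9): their
#'   non-zero conditional moments are dominated by dropout, the situation
#'   the pruning step is designed to avoid.
#' @return A [calibration_params()] object; attribute \code{fit} carries
#'   goodness-of-fit summaries (gamma log-likelihoods, f1/f2 R-squared,
#'   number of genes used) and flags.
#' @export
estimate_calibration <- function(matrix, corr_threshold = 0.25,
                                 max_genes = 500, n_draws = 1000,
                                 seed = NULL,
                                 convention = c("CLASSICAL", "AS_PRINTED"),
                                 dispersion_floor = 1e-2, mean_floor = 1e-3,
                                 zero_fraction_cap = 0.9) {
  convention <- match.arg(convention)
  stopifnot(inherits(matrix, "multigene_matrix"))
  if (length(unique(matrix$cell_metadata$individual_id)) < 2)
    stop("calibration needs >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)

  m <- filter_expressed_genes(matrix)
  genes <- prune_correlated_genes(m, corr_threshold, max_genes)
  if (length(genes) < 10)
    stop("calibration unstable: only ", length(genes),
         " gene(s) survive pruning")

  grand_means <- numeric(length(genes))
  inter_vars <- numeric(length(genes))
  zero_fracs <- numeric(length(genes))
  disp <- list(); lmu <- list()
  for (i in seq_along(genes)) {
    mom <- estimate_gene_moments(m, genes[i], n_draws = n_draws,
                                 convention = convention,
                                 dispersion_floor = dispersion_floor)
    grand_means[i] <- mom$grand_mean
    inter_vars[i] <- mom$inter_individual_variance
    zero_fracs[i] <- mom$zero_fraction
    ok <- is.finite(mom$dispersions) & is.finite(mom$within_sample_means) &
      !is.na(mom$dispersions) & mom$dispersions < 1e5
    disp[[i]] <- mom$dispersions[ok]
    lmu[[i]] <- log(mom$within_sample_means[ok])
  }

  gam_gm <- fitdistrplus::fitdist(grand_means, "gamma", method = "mle",
                                  lower = c(1e-8, 1e-8))
  use <- zero_fracs <= zero_fraction_cap & is.finite(inter_vars)
  if (sum(use) < 10)
    stop("calibration unstable: fewer than 10 genes below the ",
         "zero-fraction cap")
  f1_fit <- stats::lm(inter_vars[use] ~ grand_means[use])
  f1_neg_slope <- unname(stats::coef(f1_fit)[2]) < 0

  d <- unlist(disp[use]); l <- unlist(lmu[use])
  keep <- is.finite(d) & is.finite(l)
  # the moment estimator of the NB size is heavy-tailed to the right
  # (variance estimates near the mean explode the ratio); trim the top
  # tail so a handful of unstable pairs cannot dominate the fit
  cap <- stats::quantile(d[keep], 0.95, na.rm = TRUE)
  keep <- keep & d <= cap
  f2_fit <- stats::lm(d[keep] ~ l[keep])

  zf <- zero_fracs[zero_fracs > 0]
  n_zero_dropped <- sum(zero_fracs == 0)
  if (length(zf) < 5)
    stop("calibration unstable: fewer than 5 genes with nonzero dropout")
  gam_dp <- fitdistrplus::fitdist(zf, "gamma", method = "mle",
                                  lower = c(1e-8, 1e-8))

  params <- calibration_params(
    grand_mean_shape = gam_gm$estimate[["shape"]],
    grand_mean_rate = gam_gm$estimate[["rate"]],
    f1_intercept = unname(stats::coef(f1_fit)[1]),
    f1_slope = unname(stats::coef(f1_fit)[2]),
    f2_intercept = unname(stats::coef(f2_fit)[1]),
    f2_slope = unname(stats::coef(f2_fit)[2]),
    dropout_shape = gam_dp$estimate[["shape"]],
    dropout_rate = gam_dp$estimate[["rate"]],
    dispersion_floor = dispersion_floor, mean_floor = mean_floor)
  attr(params, "fit") <- list(
    n_genes = length(genes), genes = genes, convention = convention,
    grand_mean_loglik = gam_gm$loglik,
    dropout_loglik = gam_dp$loglik,
    f1_r_squared = summary(f1_fit)$r.squared,
    f2_r_squared = summary(f2_fit)$r.squared,
    f1_negative_slope = f1_neg_slope,
    n_zero_dropout_genes = n_zero_dropped)
  if (f1_neg_slope)
    warning("fitted inter-individual variance slope is negative")
  params
}
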