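#' Negative-binomial dispersion from a mean and variance
#'
#' Two conventions are supported. \code{"CLASSICAL"} returns the
#' negative-binomial size parameter \code{mu^2 / (sigma^2 - mu)}, the
#' quantity the NB sampler consumes (variance = mu + mu^2/size).
#' \code{"AS_PRINTED"} returns \code{mu^2 / sigma^2 - mu}, the
#' moment-expression form retained for reproducing estimation output.
#'
#' @param mean Positive mean of the non-zero values.
#' @param variance Positive variance of the non-zero values.
#' @param convention \code{"CLASSICAL"} (default) or \code{"AS_PRINTED"}.
#' @param dispersion_floor Results below this clamp are lifted to it and
#'   flagged.
#' @param underdispersed_size Finite size used when \code{"CLASSICAL"} is
#'   requested but \code{variance <= mean} (Poisson-like data; the size
#'   parameter diverges).
#' @return Numeric dispersion with attributes \code{clamped} and
#'   \code{underdispersed} (logicals).
#' @export
dispersion_from_moments <- function(mean, variance,
                                    convention = c("CLASSICAL", "AS_PRINTED"),
                                    dispersion_floor = 1e-2,
                                    underdispersed_size = 1e6) {
  convention <- match.arg(convention)
  stopifnot(mean > 0, variance > 0)
  underdispersed <- FALSE
  if (convention == "AS_PRINTED") {
    disp <- mean^2 / variance - mean
  } else {
    if (variance <= mean) {
      underdispersed <- TRUE
      disp <- underdispersed_size
    } else {
      disp <- mean^2 / (variance - mean)
    }
  }
  clamped <- is.finite(disp) && disp < dispersion_floor
  if (clamped) disp <- dispersion_floor
  structure(disp, clamped = clamped, underdispersed = underdispersed)
}

#' Hierarchical moment summary of one gene
#'
#' Estimates the grand mean by repeatedly drawing one cell per individual
#' and averaging (decoupling the estimate from the within-individual
#' correlation), and computes per-individual means, variances and
#' dispersions of the non-zero values, the variance between the individual
#' means, and the overall zero fraction.
#'
#' @param matrix A [multigene_matrix()].
#' @param gene Gene id or row index.
#' @param n_draws Number of one-cell-per-individual draws for the grand
#'   mean (default 1000).
#' @param convention Dispersion convention, see [dispersion_from_moments()].
#' @param dispersion_floor Clamp for per-individual dispersions.
#' @return An object of class \code{"gene_moments"}: list with
#'   \code{grand_mean}, \code{within_sample_means},
#'   \code{within_sample_variances}, \code{inter_individual_variance},
#'   \code{dispersions}, \code{zero_fraction}.
#' @export
estimate_gene_moments <- function(matrix, gene, n_draws = 1000,
                                  convention = c("CLASSICAL", "AS_PRINTED"),
                                  dispersion_floor = 1e-2) {
  convention <- match.arg(convention)
  stopifnot(inherits(matrix, "multigene_matrix"))
  if (is.character(gene)) {
    gi <- match(gene, matrix$gene_ids)
    if (is.na(gi)) stop("gene not found: ", gene)
  } else gi <- gene
  vals <- matrix$counts[gi, ]
  ind <- matrix$cell_metadata$individual_id
  inds <- unique(ind)
  if (length(inds) < 2)
    stop("hierarchical moments need >= 2 individuals")
  if (all(vals == 0))
    stop("gene is all-zero; exclude before moment estimation")

  by_ind <- split(vals, factor(ind, levels = inds))
  # grand mean: mean of n_draws one-cell-per-individual means
  draw_means <- vapply(seq_len(n_draws), function(d) {
    mean(vapply(by_ind, function(v) v[sample.int(length(v), 1L)], 0))
  }, 0)
  grand_mean <- mean(draw_means)

  wm <- wv <- disp <- rep(NA_real_, length(inds))
  names(wm) <- names(wv) <- names(disp) <- inds
  for (j in seq_along(inds)) {
    nz <- by_ind[[j]][by_ind[[j]] > 0]
    if (length(nz) >= 1) wm[j] <- mean(nz)
    if (length(nz) >= 2) {
      wv[j] <- stats::var(nz)
      if (wm[j] > 0 && wv[j] > 0)
        disp[j] <- as.numeric(dispersion_from_moments(
          wm[j], wv[j], convention, dispersion_floor))
    }
  }
  structure(list(
    grand_mean = grand_mean,
    within_sample_means = wm,
    within_sample_variances = wv,
    inter_individual_variance = stats::var(wm[!is.na(wm)]),
    dispersions = disp,
    zero_fraction = mean(vals == 0)), class = "gene_moments")
}

#' @export
print.gene_moments <- function(x, ...) {
  cat(sprintf(
    "gene_moments: grand mean %.3g, inter-individual var %.3g, zero fraction %.3f\n",
    x$grand_mean, x$inter_individual_variance, x$zero_fraction))
  invisible(x)
}
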