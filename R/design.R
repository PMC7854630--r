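#' Experimental design of one simulated dataset
#'
#' Describes a two-group design: individuals per group, the model for the
#' number of cells captured per individual, and the spiked fold change.
#'
#' @param n_per_group Individuals per treatment group (two groups). Values
#'   below 2 are accepted with a warning (most estimators are then
#'   degenerate).
#' @param cell_count_model \code{"FIXED"}, \code{"POISSON"} or
#'   \code{"NEGBIN"}: constant cells per individual, Poisson(lambda) slight
#'   imbalance, or negative-binomial (mean lambda, dispersion
#'   \code{negbin_dispersion}) heavy imbalance.
#' @param expected_cells Expected cells per individual (lambda), >= 1.
#' @param negbin_dispersion NB size for the cell-count model (default 1).
#' @param fold_change Multiplicative group effect on the grand mean, > 0;
#'   1 is the null.
#' @param random_direction If \code{TRUE} the spiked group is chosen by a
#'   fair coin so the direction of effect varies between groups.
#' @return An object of class \code{"design_spec"}.
#' @export
design_spec <- function(n_per_group = 5,
                        cell_count_model = c("POISSON", "FIXED", "NEGBIN"),
                        expected_cells = 100,
                        negbin_dispersion = 1,
                        fold_change = 1,
                        random_direction = FALSE) {
  cell_count_model <- match.arg(cell_count_model)
  stopifnot(n_per_group >= 1, expected_cells >= 1, fold_change > 0,
            negbin_dispersion > 0)
  if (n_per_group < 2)
    warning("n_per_group < 2: inter-individual variance is not estimable")
  structure(list(n_per_group = as.integer(n_per_group),
                 cell_count_model = cell_count_model,
                 expected_cells = expected_cells,
                 negbin_dispersion = negbin_dispersion,
                 fold_change = fold_change,
                 random_direction = isTRUE(random_direction)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "design_spec: %d individuals/group, cells ~ %s(%g), fold change %g%s\n",
    x$n_per_group, x$cell_count_model, x$expected_cells, x$fold_change,
    if (x$random_direction) " (random direction)" else ""))
  invisible(x)
}

#' Draw the number of cells per individual
#'
#' Zero draws are resampled up to a minimum of one cell (an unobserved
#' individual breaks every estimator); resampled draws are flagged.
#'
#' @param design A [design_spec()].
#' @param n_individuals Number of individuals to draw for.
#' @return Integer vector of cell counts with attribute \code{resampled}
#'   (number of zero draws lifted to 1).
#' @export
draw_cell_counts <- function(design, n_individuals) {
  stopifnot(inherits(design, "design_spec"), n_individuals >= 1)
  lambda <- design$expected_cells
  n <- switch(design$cell_count_model,
    FIXED = rep.int(as.integer(round(lambda)), n_individuals),
    POISSON = stats::rpois(n_individuals, lambda),
    NEGBIN = stats::rnbinom(n_individuals, mu = lambda,
                            size = design$negbin_dispersion))
  resampled <- sum(n == 0)
  n[n == 0] <- 1L
  structure(as.integer(n), resampled = resampled)
}
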