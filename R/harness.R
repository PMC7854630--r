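# Monte-Carlo evaluation harness: type-1-error, power and rank-order
# experiments over a simulation grid and the method registry, with
# per-replicate seed substreams and explicit failure accounting.

#' Simulation grid for the evaluation experiments
#'
#' @param n_per_group_levels Individuals per group levels
#'   (default c(5, 10, 20, 30, 40)).
#' @param expected_cells_levels Expected cells per individual levels
#'   (default c(50, 100, 250, 500)).
#' @param cell_count_model \code{"POISSON"} (default), \code{"FIXED"} or
#'   \code{"NEGBIN"}.
#' @param n_reps Replicates per condition.
#' @param alphas Significance thresholds
#'   (default c(0.05, 0.01, 0.001, 0.0001)).
#' @param methods Character vector of registry ids, or a named list of
#'   functions \code{fn(cells) -> de_outcome} (stubs allowed).
#' @param master_seed Master RNG seed; per-replicate seeds are derived
#'   from it so method order never affects results.
#' @return An object of class \code{"experiment_grid"}.
#' @export
experiment_grid <- function(n_per_group_levels = c(5, 10, 20, 30, 40),
                            expected_cells_levels = c(50, 100, 250, 500),
                            cell_count_model = "POISSON",
                            n_reps = 2000,
                            alphas = c(0.05, 0.01, 0.001, 0.0001),
                            methods = c("hurdle_fixed", "pseudobulk_mean",
                                        "pseudobulk_sum", "gee1"),
                            master_seed = 1L) {
  stopifnot(n_reps >= 1, all(alphas > 0), all(alphas < 1))
  structure(list(n_per_group_levels = n_per_group_levels,
                 expected_cells_levels = expected_cells_levels,
                 cell_count_model = cell_count_model,
                 n_reps = as.integer(n_reps), alphas = alphas,
                 methods = methods, master_seed = as.integer(master_seed)),
            class = "experiment_grid")
}

# Per-replicate seed substream: one draw of the master stream per
# replicate, so experiments parallelize and method order is irrelevant.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  s
}

resolve_methods <- function(methods) {
  if (is.character(methods)) return(de_method_registry(methods))
  stopifnot(is.list(methods), !is.null(names(methods)))
  methods
}

#' Wilson score interval for a rejection rate
#'
#' @param rejections Number of rejections, \code{0 <= rejections <= n}.
#' @param n Number of converged replicates.
#' @param level Confidence level (default 0.95).
#' @return List with \code{rate}, \code{lower}, \code{upper}.
#' @export
error_rate_with_ci <- function(rejections, n, level = 0.95) {
  stopifnot(rejections >= 0, rejections <= n, n > 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- rejections / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(rate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# Run every method on one simulated gene; returns named p-value vector
# (NA = failure).
run_methods_once <- function(dataset, methods) {
  cells <- cell_observations(dataset)
  vapply(names(methods), function(m) {
    out <- tryCatch(methods[[m]](cells),
                    error = function(e) failed_outcome(m, conditionMessage(e)))
    if (isTRUE(out$converged)) out$p_value else NA_real_
  }, 0)
}

#' Type-1-error experiment
#'
#' For every (individuals per group, expected cells) condition of the
#' grid, simulates a null gene (fold change 1) per replicate, applies
#' every method, and tallies rejections at each significance threshold.
#' Failed fits are excluded from denominators and counted separately; a
#' method failing on more than half the replicates in a condition is
#' flagged unreliable.
#'
#' @param params A [calibration_params()] object.
#' @param grid An [experiment_grid()].
#' @param dispersion_on Passed to [simulate_gene()].
#' @return Data frame of class \code{"error_rate_table"} with one row per
#'   (method, condition, alpha): rejection rate, Wilson 95% CI,
#'   \code{n_converged}, \code{n_failed}, \code{unreliable}.
#' @export
run_type1_experiment <- function(params, grid,
                                 dispersion_on = c("grand", "individual")) {
  dispersion_on <- match.arg(dispersion_on)
  methods <- resolve_methods(grid$methods)
  rows <- list()
  for (npg in grid$n_per_group_levels) {
    for (ec in grid$expected_cells_levels) {
      design <- design_spec(n_per_group = npg,
                            cell_count_model = grid$cell_count_model,
                            expected_cells = ec, fold_change = 1)
      cond_seed <- grid$master_seed + 7919L * match(npg, grid$n_per_group_levels) +
        104729L * match(ec, grid$expected_cells_levels)
      seeds <- derive_seeds(cond_seed, grid$n_reps)
      pmat <- matrix(NA_real_, grid$n_reps, length(methods),
                     dimnames = list(NULL, names(methods)))
      for (r in seq_len(grid$n_reps)) {
        ds <- simulate_gene(params, design, dispersion_on, seed = seeds[r])
        pmat[r, ] <- run_methods_once(ds, methods)
      }
      for (m in names(methods)) {
        p <- pmat[, m]
        n_ok <- sum(!is.na(p))
        n_fail <- sum(is.na(p))
        for (a in grid$alphas) {
          if (n_ok > 0) {
            ci <- error_rate_with_ci(sum(p[!is.na(p)] <= a), n_ok)
          } else ci <- list(rate = NA_real_, lower = NA_real_, upper = NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, n_per_group = npg, expected_cells = ec, alpha = a,
            rate = ci$rate, ci_lower = ci$lower, ci_upper = ci$upper,
            n_converged = n_ok, n_failed = n_fail,
            unreliable = n_fail > grid$n_reps / 2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_rate_table", class(out))
  out
}

#' Power experiment over a fold-change grid
#'
#' Power (rejection rate at \code{alpha}) per fold change and condition,
#' with the spiked group chosen by a fair coin. At fold change 1 power
#' equals the type-1 rate by construction.
#'
#' @inheritParams run_type1_experiment
#' @param fc_min,fc_max,fc_step Fold-change grid (default 1 to 5 by 0.25;
#'   the paper-scale 0.01 step is configurable but cluster-scale).
#' @param alpha Significance threshold for power (default 0.05).
#' @return Data frame of class \code{"power_curve"}: one row per
#'   (method, condition, fold_change) with power and Wilson CI.
#' @export
run_power_experiment <- function(params, grid, fc_min = 1, fc_max = 5,
                                 fc_step = 0.25, alpha = 0.05,
                                 dispersion_on = c("grand", "individual")) {
  dispersion_on <- match.arg(dispersion_on)
  stopifnot(fc_min > 0, fc_max >= fc_min, fc_step > 0)
  methods <- resolve_methods(grid$methods)
  fcs <- seq(fc_min, fc_max, by = fc_step)
  rows <- list()
  for (npg in grid$n_per_group_levels) {
    for (ec in grid$expected_cells_levels) {
      for (fi in seq_along(fcs)) {
        design <- design_spec(n_per_group = npg,
                              cell_count_model = grid$cell_count_model,
                              expected_cells = ec, fold_change = fcs[fi],
                              random_direction = TRUE)
        cond_seed <- grid$master_seed +
          7919L * match(npg, grid$n_per_group_levels) +
          104729L * match(ec, grid$expected_cells_levels) + 15485863L * fi
        seeds <- derive_seeds(cond_seed, grid$n_reps)
        pmat <- matrix(NA_real_, grid$n_reps, length(methods),
                       dimnames = list(NULL, names(methods)))
        for (r in seq_len(grid$n_reps)) {
          ds <- simulate_gene(params, design, dispersion_on, seed = seeds[r])
          pmat[r, ] <- run_methods_once(ds, methods)
        }
        for (m in names(methods)) {
          p <- pmat[, m]
          n_ok <- sum(!is.na(p))
          ci <- if (n_ok > 0) error_rate_with_ci(sum(p[!is.na(p)] <= alpha), n_ok)
                else list(rate = NA_real_, lower = NA_real_, upper = NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, n_per_group = npg, expected_cells = ec,
            fold_change = fcs[fi], power = ci$rate,
            ci_lower = ci$lower, ci_upper = ci$upper,
            n_converged = n_ok, n_failed = grid$n_reps - n_ok,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", class(out))
  out
}

#' Rank-order preservation experiment
#'
#' Simulates genes with fold changes drawn uniformly, runs each method,
#' and reports the Spearman correlation between each method's p-value
#' ranking and the absolute simulated log fold change (signed so a
#' perfect method scores +1), plus per-fold-change-bin sensitivity at
#' \code{alpha}.
#'
#' @param params A [calibration_params()] object.
#' @param n_genes Number of simulated genes (default 2000).
#' @param fc_low,fc_high Uniform fold-change range (default 0 to 4).
#' @param n_per_group Individuals per group (default 30).
#' @param expected_cells Expected cells per individual (default 100).
#' @param methods Registry ids or named list of functions.
#' @param alpha Threshold for the sensitivity-by-bin summary.
#' @param seed Master seed.
#' @param dispersion_on Passed to [simulate_gene()].
#' @return List of class \code{"rank_order_report"}: \code{rank_correlation}
#'   (named per method), \code{sensitivity_by_bin} data frame,
#'   \code{p_values} matrix, \code{fold_changes}.
#' @export
run_rank_order_experiment <- function(params, n_genes = 2000,
                                      fc_low = 0, fc_high = 4,
                                      n_per_group = 30, expected_cells = 100,
                                      methods = c("hurdle_fixed",
                                                  "hurdle_corrected",
                                                  "pseudobulk_mean"),
                                      alpha = 0.05, seed = 1L,
                                      dispersion_on = c("grand", "individual")) {
  dispersion_on <- match.arg(dispersion_on)
  mfuns <- resolve_methods(methods)
  seeds <- derive_seeds(seed, n_genes)
  fc_seeds <- derive_seeds(seed + 1L, 1L)
  set.seed(fc_seeds)
  fcs <- stats::runif(n_genes, fc_low, fc_high)
  pmat <- matrix(NA_real_, n_genes, length(mfuns),
                 dimnames = list(NULL, names(mfuns)))
  for (g in seq_len(n_genes)) {
    design <- design_spec(n_per_group = n_per_group,
                          cell_count_model = "POISSON",
                          expected_cells = expected_cells,
                          fold_change = max(fcs[g], 1e-6),
                          random_direction = TRUE)
    ds <- simulate_gene(params, design, dispersion_on, seed = seeds[g])
    pmat[g, ] <- run_methods_once(ds, mfuns)
  }
  alfc <- abs(log(pmax(fcs, 1e-6)))
  rc <- vapply(colnames(pmat), function(m) {
    ok <- !is.na(pmat[, m])
    if (sum(ok) < 3) return(NA_real_)
    -stats::cor(pmat[ok, m], alfc[ok], method = "spearman")
  }, 0)
  bins <- cut(fcs, breaks = seq(fc_low, fc_high, by = 0.5),
              include.lowest = TRUE)
  sens <- do.call(rbind, lapply(levels(bins), function(b) {
    i <- bins == b
    data.frame(bin = b, n = sum(i),
               t(vapply(colnames(pmat), function(m) {
                 ok <- i & !is.na(pmat[, m])
                 if (!sum(ok)) return(NA_real_)
                 mean(pmat[ok, m] <= alpha)
               }, 0)), check.names = FALSE, stringsAsFactors = FALSE)
  }))
  structure(list(rank_correlation = rc, sensitivity_by_bin = sens,
                 p_values = pmat, fold_changes = fcs),
            class = "rank_order_report")
}

#' @export
print.rank_order_report <- function(x, ...) {
  cat("rank_order_report: Spearman(p-rank, |log FC|):\n")
  print(round(x$rank_correlation, 3))
  invisible(x)
}

#' Sensitivity and specificity summary
#'
#' Sensitivity is the rejection rate among converged non-null replicates;
#' specificity is one minus the type-1 rate from the matched null run.
#'
#' @param p_values Numeric p-value vector (NA = failed fit).
#' @param is_null Logical truth label per replicate.
#' @param alpha Significance threshold.
#' @param null_type1_rate Type-1 rate of the matched null experiment; if
#'   missing it is computed from the null replicates in \code{p_values}.
#' @return List with \code{sensitivity}, \code{specificity},
#'   \code{n_true}, \code{n_null}; sensitivity is \code{NA} (flagged) when
#'   there are no non-null replicates.
#' @export
sensitivity_specificity <- function(p_values, is_null, alpha = 0.05,
                                    null_type1_rate = NULL) {
  stopifnot(length(p_values) == length(is_null))
  ok <- !is.na(p_values)
  pos <- ok & !is_null
  sens <- if (any(pos)) mean(p_values[pos] <= alpha) else NA_real_
  if (is.null(null_type1_rate)) {
    nul <- ok & is_null
    null_type1_rate <- if (any(nul)) mean(p_values[nul] <= alpha) else NA_real_
  }
  list(sensitivity = sens, specificity = 1 - null_type1_rate,
       n_true = sum(pos), n_null = sum(ok & is_null))
}
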