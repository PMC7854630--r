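#' Registry of differential-expression methods
#'
#' Every method is callable uniformly as \code{fn(cells)} on a
#' [cell_observations()] object and returns a [de_outcome()].
#'
#' @param methods Optional character vector selecting a subset.
#' @return Named list of method functions. Available ids:
#'   \code{hurdle_fixed}, \code{hurdle_corrected}, \code{hurdle_mixed},
#'   \code{tweedie_glm}, \code{gee1}, \code{pseudobulk_mean},
#'   \code{pseudobulk_sum}, \code{tobit}.
#' @export
de_method_registry <- function(methods = NULL) {
  reg <- list(
    hurdle_fixed = hurdle_fixed_test,
    hurdle_corrected = hurdle_corrected_test,
    hurdle_mixed = hurdle_mixed_test,
    tweedie_glm = tweedie_glm_test,
    gee1 = gee1_test,
    pseudobulk_mean = function(cells) pseudobulk_test(cells, "MEAN"),
    pseudobulk_sum = function(cells) pseudobulk_test(cells, "SUM"),
    tobit = tobit_test)
  if (is.null(methods)) return(reg)
  unknown <- setdiff(methods, names(reg))
  if (length(unknown)) stop("unknown method(s): ",
                            paste(unknown, collapse = ", "))
  reg[methods]
}

#' Run a set of methods on one dataset
#'
#' @param dataset A [simulate_gene()] result (or compatible list).
#' @param methods Character vector of registry ids (default: all).
#' @return Data frame, one row per method (see [outcomes_table()]).
#' @export
run_de_methods <- function(dataset, methods = NULL) {
  reg <- de_method_registry(methods)
  cells <- cell_observations(dataset)
  outcomes_table(lapply(names(reg), function(m) {
    out <- tryCatch(reg[[m]](cells),
                    error = function(e) failed_outcome(m, conditionMessage(e)))
    out$method <- m
    out
  }))
}
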