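#' Construct a differential-expression test outcome
#'
#' Uniform result container for all methods in the registry. A
#' non-converged outcome must carry a failure reason and no p-value.
#'
#' @param method Method identifier string.
#' @param p_value P-value in [0, 1], or \code{NA} if the fit failed.
#' @param statistic Test statistic (chi-square or Wald z, by method).
#' @param effect_estimate Group-effect estimate on the method's scale.
#' @param converged Logical.
#' @param failure_reason \code{NA_character_} or a short reason string.
#' @param components Optional list of component details (e.g. the hurdle
#'   model's per-component chi-squares and degrees of freedom).
#' @return An object of class \code{"de_outcome"}.
#' @export
de_outcome <- function(method, p_value = NA_real_, statistic = NA_real_,
                       effect_estimate = NA_real_, converged = TRUE,
                       failure_reason = NA_character_, components = NULL) {
  if (!converged) {
    p_value <- NA_real_
    if (is.na(failure_reason)) failure_reason <- "unspecified failure"
  }
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(method = method, p_value = p_value, statistic = statistic,
                 effect_estimate = effect_estimate, converged = converged,
                 failure_reason = failure_reason, components = components),
            class = "de_outcome")
}

failed_outcome <- function(method, reason, components = NULL) {
  de_outcome(method, converged = FALSE, failure_reason = reason,
             components = components)
}

#' @export
print.de_outcome <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("%s: p = %.4g, statistic = %.4g, effect = %.4g\n",
                x$method, x$p_value, x$statistic, x$effect_estimate))
  } else {
    cat(sprintf("%s: FAILED (%s)\n", x$method, x$failure_reason))
  }
  invisible(x)
}

#' Bind a list of outcomes into a results table
#'
#' @param outcomes List of [de_outcome()] objects.
#' @return Data frame with columns \code{method}, \code{p_value},
#'   \code{statistic}, \code{effect_estimate}, \code{converged},
#'   \code{failure_reason}.
#' @export
outcomes_table <- function(outcomes) {
  do.call(rbind, lapply(outcomes, function(o)
    data.frame(method = o$method, p_value = o$p_value,
               statistic = o$statistic, effect_estimate = o$effect_estimate,
               converged = o$converged, failure_reason = o$failure_reason,
               stringsAsFactors = FALSE)))
}
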