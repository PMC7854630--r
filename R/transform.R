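#' Log(x + offset) transformation
#'
#' The transformation applied to expression values before the cell-level
#' tests (hurdle, GEE, Tobit, Tweedie). Zeros map to zero with the default
#' offset of 1.
#'
#' @param x Non-negative numeric values.
#' @param base Logarithm base (default 2).
#' @param offset Added before taking logs (default 1).
#' @return \code{log(x + offset, base)}.
#' @export
log_transform <- function(x, base = 2, offset = 1) {
  if (any(x < 0)) stop("log_transform requires non-negative input")
  log(x + offset, base = base)
}
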