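#' Tobit (left-censored Gaussian) test
#'
#' Latent Gaussian linear model for the log-transformed expression with
#' left censoring at 0 (zeros are treated as censored observations of a
#' latent value at or below 0), fitted by maximum likelihood
#' (\code{survival::survreg}), with a likelihood-ratio test of the group
#' coefficient. With no zeros this reduces exactly to ordinary Gaussian
#' ML regression. Treats cells as independent.
#'
#' @param cells A [cell_observations()] object.
#' @return A [de_outcome()].
#' @export
tobit_test <- function(cells) {
  method <- "tobit"
  y <- cells$y
  g <- cells$group
  if (all(y == 0)) return(failed_outcome(method, "all cells censored"))
  if (length(unique(g)) < 2) return(failed_outcome(method, "single group"))
  event <- as.integer(y > 0)  # 0 = left-censored at the zero bound
  dat <- data.frame(y = y, g = g, event = event)
  fit1 <- tryCatch(suppressWarnings(
    survival::survreg(survival::Surv(y, event, type = "left") ~ g,
                      data = dat, dist = "gaussian")),
    error = function(e) NULL)
  fit0 <- tryCatch(suppressWarnings(
    survival::survreg(survival::Surv(y, event, type = "left") ~ 1,
                      data = dat, dist = "gaussian")),
    error = function(e) NULL)
  if (is.null(fit1) || is.null(fit0))
    return(failed_outcome(method, "censored Gaussian fit failed"))
  chisq <- max(0, 2 * (fit1$loglik[2] - fit0$loglik[2]))
  de_outcome(method,
             p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             statistic = chisq,
             effect_estimate = unname(stats::coef(fit1)["g"]))
}
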