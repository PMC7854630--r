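# Two-part hurdle model: a logistic model for the expression indicator and
# a Gaussian model for the positive log-expression values, combined by
# summing the per-component chi-squares and degrees of freedom.

#' Combine the two hurdle component tests
#'
#' Sums the component chi-square statistics and their degrees of freedom
#' and returns the upper-tail probability of the combined chi-square; the
#' components are conditionally independent, so the sum is asymptotically
#' chi-square. A missing component contributes (0, 0).
#'
#' @param chisq_d,df_d Discrete (logistic) component statistic and df.
#' @param chisq_c,df_c Continuous (Gaussian) component statistic and df.
#' @return P-value, or \code{NA} if both degrees of freedom are zero.
#' @export
combine_component_tests <- function(chisq_d, df_d, chisq_c, df_c) {
  if (is.na(chisq_d) || is.na(df_d)) { chisq_d <- 0; df_d <- 0 }
  if (is.na(chisq_c) || is.na(df_c)) { chisq_c <- 0; df_c <- 0 }
  stopifnot(chisq_d >= 0, chisq_c >= 0, df_d >= 0, df_c >= 0)
  df <- df_d + df_c
  if (df == 0) return(NA_real_)
  stats::pchisq(chisq_d + chisq_c, df = df, lower.tail = FALSE)
}

# Group-level quasi/complete separation of the indicator: z varies overall
# but is constant within at least one group.
detect_separation <- function(z, group) {
  if (length(unique(z)) < 2) return(FALSE)
  any(vapply(split(z, group), function(v) length(unique(v)) < 2, TRUE))
}

# Continuous-component LRT under Gaussian ML: n * log(RSS0 / RSS1).
gaussian_lrt <- function(y, group) {
  n <- length(y)
  rss1 <- sum(stats::lm.fit(cbind(1, group), y)$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  if (rss1 <= 0) return(list(chisq = Inf, beta = NA_real_))
  beta <- stats::coef(stats::lm.fit(cbind(1, group), y))[2]
  list(chisq = max(0, n * log(rss0 / rss1)), beta = unname(beta))
}

#' Two-part hurdle test without random effects
#'
#' Logistic regression of the expression indicator on group plus Gaussian
#' regression of the positive log-expression values on group, each tested
#' by a likelihood-ratio chi-square for the group coefficient, combined by
#' [combine_component_tests()]. Treats cells as independent: this is the
#' naive analysis whose type-1 error inflates under within-individual
#' correlation.
#'
#' @param cells A [cell_observations()] object.
#' @return A [de_outcome()] with component statistics in
#'   \code{$components}.
#' @export
hurdle_fixed_test <- function(cells) {
  method <- "hurdle_fixed"
  z <- cells$z; y <- cells$y; g <- cells$group
  if (length(unique(g)) < 2)
    return(failed_outcome(method, "single group"))
  if (all(z == 0))
    return(failed_outcome(method, "all cells zero"))
  if (detect_separation(z, g))
    return(failed_outcome(method, "separation in discrete component"))

  chisq_d <- df_d <- NA_real_
  beta_d <- NA_real_
  if (length(unique(z)) == 2) {
    fit1 <- stats::glm.fit(cbind(1, g), z, family = stats::binomial())
    dev0 <- stats::glm.fit(matrix(1, length(z)), z,
                           family = stats::binomial())$deviance
    chisq_d <- max(0, dev0 - fit1$deviance)
    df_d <- 1
    beta_d <- unname(stats::coef(fit1)[2])
  }

  chisq_c <- df_c <- NA_real_
  beta_c <- NA_real_
  pos <- z == 1
  if (sum(pos) >= 3 && length(unique(g[pos])) == 2) {
    if (stats::var(y[pos]) > 0) {
      lrt <- gaussian_lrt(y[pos], g[pos])
      chisq_c <- lrt$chisq
      df_c <- 1
      beta_c <- lrt$beta
    } else {
      # constant positive values: a zero group effect, not a failure
      chisq_c <- 0; df_c <- 1; beta_c <- 0
    }
  }

  p <- combine_component_tests(chisq_d, df_d, chisq_c, df_c)
  if (is.na(p))
    return(failed_outcome(method, "both components degenerate"))
  comp <- list(chisq_discrete = chisq_d, df_discrete = df_d,
               chisq_continuous = chisq_c, df_continuous = df_c)
  de_outcome(method, p_value = p,
             statistic = sum(c(chisq_d, chisq_c), na.rm = TRUE),
             effect_estimate = if (!is.na(beta_c)) beta_c else beta_d,
             components = comp)
}

#' Logistic regression with a per-individual random intercept
#'
#' Fits \code{z ~ group + (1 | individual)} by maximizing the marginal
#' likelihood with the normal random intercept integrated out by adaptive
#' Gauss-Hermite quadrature (Laplace when \code{quadrature_points = 1}),
#' together with the null model without the group term, for a
#' likelihood-ratio test.
#'
#' @param z 0/1 expression indicator per cell.
#' @param x 0/1 group label per cell.
#' @param individual Factor of individual labels.
#' @param quadrature_points Number of adaptive Gauss-Hermite points
#'   (default 1 = Laplace approximation).
#' @return List with \code{beta} (intercept, group), \code{re_variance},
#'   \code{loglik}, \code{loglik_null}, \code{chisq}, \code{df},
#'   \code{converged}, \code{failure_reason}.
#' @export
fit_logistic_random_intercept <- function(z, x, individual,
                                          quadrature_points = 1) {
  fail <- function(msg) list(beta = c(NA, NA), re_variance = NA_real_,
                             loglik = NA_real_, loglik_null = NA_real_,
                             chisq = NA_real_, df = NA_real_,
                             converged = FALSE, failure_reason = msg)
  if (length(unique(z)) < 2) return(fail("indicator constant"))
  dat <- data.frame(z = z, x = x, individual = individual)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(z ~ x + (1 | individual), data = dat,
                family = stats::binomial(), nAGQ = quadrature_points))),
    error = function(e) NULL)
  fit0 <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(z ~ 1 + (1 | individual), data = dat,
                family = stats::binomial(), nAGQ = quadrature_points))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit0)) return(fail("glmer did not converge"))
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  if (!is.finite(ll1) || !is.finite(ll0))
    return(fail("non-finite marginal likelihood"))
  list(beta = unname(lme4::fixef(fit)),
       re_variance = unname(lme4::VarCorr(fit)$individual[1, 1]),
       loglik = ll1, loglik_null = ll0,
       chisq = max(0, 2 * (ll1 - ll0)), df = 1,
       converged = TRUE, failure_reason = NA_character_)
}

#' Gaussian linear mixed model with a per-individual random intercept
#'
#' Fits \code{y ~ group + (1 | individual)} by maximum likelihood (not
#' REML, so likelihood-ratio tests on the fixed effect are valid), on the
#' positive cells only.
#'
#' @param y Log-scale expression per cell (positive cells).
#' @param x 0/1 group label per cell.
#' @param individual Factor of individual labels.
#' @return List with \code{beta}, \code{re_variance}, \code{resid_variance},
#'   \code{loglik}, \code{loglik_null}, \code{chisq}, \code{df},
#'   \code{converged}, \code{failure_reason}.
#' @export
fit_linear_random_intercept <- function(y, x, individual) {
  fail <- function(msg) list(beta = c(NA, NA), re_variance = NA_real_,
                             resid_variance = NA_real_,
                             loglik = NA_real_, loglik_null = NA_real_,
                             chisq = NA_real_, df = NA_real_,
                             converged = FALSE, failure_reason = msg)
  individual <- droplevels(factor(individual))
  per_group <- tapply(as.character(individual), x,
                      function(v) length(unique(v)))
  # one individual per group is tolerated (wide CI, not an error); a group
  # with no positive cells is not
  if (length(per_group) < 2 || any(per_group < 1) || nlevels(individual) < 2)
    return(fail("a group has no individuals with positive cells"))
  if (stats::var(y) == 0) return(fail("response constant"))
  dat <- data.frame(y = y, x = x, individual = individual)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | individual), data = dat, REML = FALSE))),
    error = function(e) NULL)
  fit0 <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | individual), data = dat, REML = FALSE))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit0)) return(fail("lmer did not converge"))
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  list(beta = unname(lme4::fixef(fit)),
       re_variance = unname(lme4::VarCorr(fit)$individual[1, 1]),
       resid_variance = stats::sigma(fit)^2,
       loglik = ll1, loglik_null = ll0,
       chisq = max(0, 2 * (ll1 - ll0)), df = 1,
       converged = TRUE, failure_reason = NA_character_)
}

#' Two-part hurdle test with per-individual random intercepts
#'
#' The discrete component is a logistic GLMM
#' ([fit_logistic_random_intercept()]) and the continuous component a
#' Gaussian LMM on the positive cells ([fit_linear_random_intercept()]);
#' each contributes a group-effect likelihood-ratio chi-square, combined by
#' [combine_component_tests()]. Non-convergence of either component flags
#' the outcome as failed (failures are counted separately by the harness,
#' never folded into rejection denominators).
#'
#' @param cells A [cell_observations()] object.
#' @param quadrature_points Passed to [fit_logistic_random_intercept()].
#' @return A [de_outcome()].
#' @export
hurdle_mixed_test <- function(cells, quadrature_points = 1) {
  method <- "hurdle_mixed"
  z <- cells$z; y <- cells$y; g <- cells$group; ind <- cells$individual
  if (length(unique(g)) < 2)
    return(failed_outcome(method, "single group"))
  if (all(z == 0))
    return(failed_outcome(method, "all cells zero"))
  if (detect_separation(z, g))
    return(failed_outcome(method, "separation in discrete component"))

  chisq_d <- df_d <- NA_real_
  comp_d <- NULL
  if (length(unique(z)) == 2) {
    comp_d <- fit_logistic_random_intercept(z, g, ind, quadrature_points)
    if (!comp_d$converged)
      return(failed_outcome(method, paste0("discrete: ", comp_d$failure_reason)))
    chisq_d <- comp_d$chisq; df_d <- comp_d$df
  }

  pos <- z == 1
  chisq_c <- df_c <- NA_real_
  comp_c <- NULL
  if (sum(pos) >= 4 && length(unique(g[pos])) == 2) {
    if (stats::var(y[pos]) == 0) {
      chisq_c <- 0; df_c <- 1
      comp_c <- list(beta = c(y[pos][1], 0))
    } else {
      comp_c <- fit_linear_random_intercept(y[pos], g[pos], ind[pos])
      if (!comp_c$converged)
        return(failed_outcome(method, paste0("continuous: ", comp_c$failure_reason)))
      chisq_c <- comp_c$chisq; df_c <- comp_c$df
    }
  }

  p <- combine_component_tests(chisq_d, df_d, chisq_c, df_c)
  if (is.na(p))
    return(failed_outcome(method, "both components degenerate"))
  de_outcome(method, p_value = p,
             statistic = sum(c(chisq_d, chisq_c), na.rm = TRUE),
             effect_estimate = if (!is.null(comp_c)) comp_c$beta[2]
                               else comp_d$beta[2],
             components = list(chisq_discrete = chisq_d, df_discrete = df_d,
                               chisq_continuous = chisq_c, df_continuous = df_c,
                               discrete = comp_d, continuous = comp_c))
}
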