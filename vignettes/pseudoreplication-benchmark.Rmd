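---
title: "Simulating hierarchical single-cell expression and benchmarking differential-expression tests under pseudoreplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hierarchical single-cell expression and benchmarking differential-expression tests under pseudoreplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdesim)
```

## The problem

Cells sampled from the same donor share a genetic and environmental
background, so their expression measurements are correlated: they are
subsamples (pseudoreplicates) of one experimental unit, not independent
replicates. A differential-expression test that treats every cell as
independent understates the variance of the group contrast and inflates
the test degrees of freedom, so its type-1 error grows with the number of
cells per donor — the more cells you sequence, the more false positives
you report. `scdesim` provides (i) a calibrated hierarchical simulator for
single-gene and matrix-mode expression data, (ii) implementations of the
commonly used cell-level and donor-level tests, and (iii) Monte-Carlo
harnesses that measure their type-1 error, power and rank-order behaviour,
plus the intra-/inter-donor correlation diagnostic that motivates the
hierarchy.

## The generative model

For each gene, independently:

1. a grand mean on the TPM scale is drawn from a gamma law,
   $\mu_i \sim \Gamma(\alpha, \beta)$;
2. each treatment group's mean is $\mu_i$ or $c\,\mu_i$ for fold change
   $c$ (the spiked group optionally chosen by a fair coin);
3. each donor $j$ receives an offset $\delta_j \sim N(0, f_1(\mu))$, with
   $f_1(\mu) = \max(0, a_1 + b_1\mu)$ the inter-individual variance
   function evaluated at that donor's group mean, giving the donor mean
   $\mu_{ij} = \mu + \delta_j$ (clamped below at `mean_floor`);
4. the negative-binomial size for the gene is
   $f_2(\mu) = a_2 + b_2\ln\mu$ (clamped below at `dispersion_floor`),
   evaluated at the group mean by default (configurable to the donor
   mean; the grand-mean reading keeps one dispersion per gene and group,
   the convention used where the count draw is defined);
5. the number of cells per donor is fixed, Poisson($\lambda$) or
   negative-binomial (mean $\lambda$, size 1) for increasing imbalance;
   zero draws are resampled to one cell, since an unobserved donor breaks
   every estimator;
6. each cell's count is $Y_{ijk} \sim \mathrm{NB}(\mu_{ij}, f_2)$, and is
   then zeroed independently with the gene's dropout probability
   $p_i \sim \Gamma$ truncated to $[0,1]$ — dropout rides on top of the
   NB zeros (thinning), is constant across donors and groups, and
   therefore never creates a group difference on its own.

Two dispersion conventions are implemented.
`dispersion_from_moments(mean, variance, "AS_PRINTED")` evaluates
$\mu^2/\sigma^2 - \mu$, the moment expression as the benchmarked
estimation pipeline writes it; `"CLASSICAL"` evaluates
$\mu^2/(\sigma^2 - \mu)$, the actual NB
size parameter for which $\mathrm{Var} = \mu + \mu^2/\mathrm{size}$. The
two disagree except on the NB variance manifold. The sampler and the
default calibration consume `"CLASSICAL"`, because that is the parameter
`rnbinom` needs; `"AS_PRINTED"` is retained so that estimation output
in the written-as-printed convention can be reproduced verbatim.

## The packaged default calibration

The constants fitted to the reference pancreatic alpha-cell data were
never published, so the package ships a versioned default
(`calibration_default()`), chosen once so that simulated data land in the
qualitative regime the published benchmark reports, and overridable
everywhere:

| constant | value | role |
|---|---|---|
| grand means | $\Gamma(0.9,\,0.02)$ | right-skewed TPM means, mean 45 |
| $f_1(\mu)$ | $12\,\mu$ | inter-donor variance; log-scale ICC $\approx$ 0.2 |
| $f_2(\mu)$ | $-0.6 + 0.45\ln\mu$ | NB size growing with expression (1–2 for typical means) |
| dropout | $\Gamma(2.5,\,10)$ | mean dropout probability 0.25 |
| floors | $10^{-2}$, $10^{-3}$ | dispersion and donor-mean clamps |

With these constants the naive cell-level hurdle rejects a true null
roughly half the time at 5 donors per group and 50 cells per donor, and
ever more often as cells are added, while donor-level aggregation stays
conservative — the published pattern. `estimate_calibration()` fits all
constants from a user matrix: gamma laws by maximum likelihood
(`fitdistrplus`), $f_1$ and $f_2$ by least squares of the per-gene /
per-donor moments, after pruning to weakly correlated genes.

Two estimation caveats are documented rather than hidden. First, genes
whose zero fraction exceeds a cap (default 0.9) are excluded from the
moment regressions — their non-zero conditional moments say more about
dropout than about the gene. Second, the moment estimator of the NB size
on non-zero values is zero-truncation-biased and heavy-tailed to the
right; the top 5% of size estimates are trimmed before the $f_2$ fit, and
even so the fitted slope is attenuated relative to a known truth in
self-simulation. The gamma laws and $f_1$ recover well (tested to 20%);
$f_2$ recovery is tested for sign and order of magnitude only.

## The test suite

All cell-level tests run on $\log_2(x+1)$-transformed values (the hurdle
convention); donor-level NB tests run on raw-count aggregates.

**Two-part hurdle** (`hurdle_fixed_test`, `hurdle_mixed_test`): a
logistic model for the expression indicator $Z$ and a Gaussian model for
the positive values, each contributing a 1-df likelihood-ratio
chi-square for the group term; the statistics and degrees of freedom are
summed (the components are conditionally independent), and the combined
upper-tail chi-square probability is the p-value. The mixed variant adds
a per-donor normal random intercept to both components: the logistic
component is integrated by adaptive Gauss–Hermite quadrature (`lme4`,
Laplace by default, `quadrature_points` configurable), the Gaussian
component is fitted by maximum likelihood (not REML) so the LRT is
valid. Likelihood-ratio rather than Wald combination is used throughout
(both are asymptotically chi-square; the LRT behaves better at the
boundary). Quasi/complete separation of the indicator
at group level, and all-zero genes, are reported as explicit failures and
counted separately by the harness — never silently folded into rejection
rates. Constant positive values are a zero group effect, not a failure.

**Pseudo-bulk** (`pseudobulk_aggregate` + `nb_wald_test`): cells are
collapsed to one value per donor (mean or sum of raw counts; means are
kept at full precision and rounded only at the NB likelihood boundary,
with a flag), then tested with an NB GLM with log link and size factors
fixed at one. The dispersion is estimated by maximizing the Cox–Reid
adjusted profile likelihood — the REML-type correction without which the
ML dispersion at 10–80 aggregates is biased low and the Wald test
anti-conservative — with a method-of-moments fallback, and the Wald
statistic is referred to a $t_{n-2}$ distribution, the appropriate
small-sample reference at donor-level sample sizes. This is deliberately
a plain NB Wald test: no cross-gene dispersion shrinkage, no outlier
machinery.

**GEE1** (`gee1_test`): Gaussian identity-link estimating equations with
an exchangeable working correlation over donors (closed-form cluster
inverse), moment estimation of the correlation, and the robust sandwich
variance. With few donors the sandwich variance is known to be too
small; the benchmark reproduces exactly that inflation.

**Tweedie GLM** (`tweedie_glm_test`): compound Poisson-gamma GLM with
log link on the transformed values (support: non-negative with a point
mass at zero, power $p \in (1,2)$). The power parameter is estimated by
continuous ML profiling (mgcv's `tw()`), a refinement of coarse-grid
profiling that estimates the same quantity; the group term is then
tested by a scaled-deviance LRT at the fixed estimated power, which
measured exactly nominal under an i.i.d. null where the Wald test with
estimated power was visibly conservative.

**Tobit** (`tobit_test`): censored-Gaussian maximum likelihood
(`survival::survreg`, left-censored at zero) with an LRT on group, the
generic censored-regression treatment of log expression popularized by
single-cell toolkits. With no zeros it reduces exactly
to ordinary Gaussian ML regression.

**Batch-corrected hurdle** (`batch_correct_individual` +
`hurdle_corrected_test`): the misuse being quantified — remove donor
effects, then treat cells as independent. `EB` mode is the parametric
empirical-Bayes location–scale adjustment with donors as batches
(delegated to `sva::ComBat`) for multi-gene input; `EXACT` mode is full
per-donor location–scale standardization, usable on the single-gene
replicates of the benchmark. How the published benchmark applied the EB
correction to single-gene replicates is not reconstructible (EB
shrinkage needs many genes), so the corrected column is reproduced
directionally — inflated relative to the random-effect hurdle — rather
than cell-for-cell.

## The evaluation harness

`run_type1_experiment`, `run_power_experiment` and
`run_rank_order_experiment` iterate `simulate_gene` over a condition grid
and the method registry. Per-replicate seeds are drawn once from the
master seed, so results are independent of method order and reproducible
exactly. Failed fits are excluded from rejection denominators and
reported alongside (`n_converged + n_failed = n_reps` always); a method
failing on more than half the replicates in a condition is flagged
unreliable. Rejection rates carry Wilson 95% intervals. Power runs
randomize the spiked group by a fair coin; at fold change 1 power equals
the type-1 rate by construction. The rank-order experiment draws
per-gene fold changes uniformly, and reports the Spearman correlation
between each method's p-value ranking and $|\log \mathrm{fc}|$, signed
so a perfect method scores $+1$, plus per-fold-change-bin sensitivity.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
scaled to desk size as the package's own defaults: 2,000 replicates for
closed-form methods, 300–500 for mixed models, 0.25-wide fold-change
steps, 100–300 genes per correlation study. The full published scale
(250,000 replicates, 0.01 fold-change steps) is available by
configuration.

## Correlation diagnostics

`correlation_diagnostic` reproduces the intra- vs inter-donor comparison:
drop zero-mean genes, greedily prune to at most 500 genes pairwise-weakly
correlated with each sampled seed gene (Spearman threshold 0.25; the
guarantee is against the sampled gene, matching the published greedy
procedure, not all-pairs), then compare all within-donor cell-pair
Spearman correlations with across-donor pairs formed by repeatedly
drawing one cell per donor. Ties get average ranks; cell pairs with a
constant profile over the gene subset are skipped and counted. On
hierarchical simulations the intra median exceeds the inter median
essentially always; with the hierarchy collapsed the two are
exchangeable and the comparison is a coin flip — both properties are in
the test suite.

## Numerical choices and edge cases

- Donor means can go non-positive after the normal offset; they are
  clamped at `mean_floor` $= 10^{-3}$.
- $f_1$ can be fitted with a negative slope on real data; it is clamped
  at zero where evaluated negative, and flagged.
- Dropout probabilities are drawn by rejection until $\le 1$ (50
  attempts, then clamped).
- The underdispersed (`CLASSICAL`, $\sigma^2 \le \mu$) case returns a
  large finite size (Poisson-like) with a flag.
- GEE's working correlation is clamped to the positive-definite range
  of the exchangeable family.
- mgcv's extended families close over an environment parented at the
  global environment; the Tweedie test repoints it at the mgcv
  namespace so the package works without mgcv attached.

## Known limitations

- The simulator models independent genes: no gene–gene correlation, no
  library-size or chemistry effects, no UMI collisions. Matrix mode
  shares one cell layout across genes purely so multi-gene consumers are
  testable; the genes are still independent draws. Passing benchmarks
  here therefore demonstrates correct behaviour under the stated
  hierarchical model, not under every feature of real data.
- $f_2$ estimation from non-zero moments is attenuated (see above); the
  packaged default was chosen directly rather than fitted.
- The published corrected-column rates are not reproducible
  cell-for-cell (EB-on-single-gene ambiguity); directional behaviour is.
- The Tweedie mixed model and the bootstrap-based modified-t are out of
  scope; no mature mixed-Tweedie machinery is depended upon, and the
  registry documents their absence.
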