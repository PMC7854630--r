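# scdesim

Hierarchical single-cell expression simulation and differential-expression
benchmarking under pseudoreplication.

## The problem

Single-cell RNA-seq experiments sequence many cells per donor, but cells
from the same donor are correlated — they are subsamples of one
experimental unit, not independent replicates. Differential-expression
tests that treat every cell as independent (the common practice)
understate the variance of the group contrast and inflate the test
degrees of freedom, so their false-positive rate grows with the number of
cells per donor. `scdesim` is for statisticians and computational
biologists who want to quantify that failure mode, compare remedies
(donor-level random effects, pseudo-bulk aggregation, GEE), and size
future studies.

## What is inside

- **Simulator** — per gene: grand mean `μ_i ~ Γ(α, β)`; donor means
  `μ_ij = μ + δ_j`, `δ_j ~ N(0, f1(μ))` with linear `f1`; cell counts
  fixed/Poisson/negative-binomial per donor; counts
  `Y_ijk ~ NB(μ_ij, f2(μ))` with logarithmic `f2` (NB size); gamma
  dropout applied as Bernoulli thinning, constant across groups. Fold
  changes spike one group's mean multiplicatively.
  `estimate_calibration()` fits all constants from a user matrix;
  `calibration_default()` ships a documented default.
- **Tests** — two-part hurdle (logistic + Gaussian components, summed
  LRT chi-squares), with and without donor random intercepts (`lme4`);
  per-donor batch-correction pipeline (empirical-Bayes location–scale /
  exact standardization) feeding the naive hurdle; pseudo-bulk mean/sum
  with an NB Wald GLM (Cox–Reid adjusted dispersion, t reference, size
  factors fixed at 1); Gaussian GEE1 with exchangeable working
  correlation and sandwich variance; Tweedie GLM (ML power estimation,
  scaled-deviance LRT); Tobit (left-censored Gaussian ML).
- **Harnesses** — type-1-error, power and rank-order Monte-Carlo
  experiments over a condition grid with per-replicate seed substreams,
  Wilson intervals and explicit failure accounting; intra- vs
  inter-donor Spearman correlation diagnostics on a pruned gene set.

## Worked example

Simulate one gene with a two-fold effect at 5 donors per group and ~50
cells per donor, and run every registered test:

```r
library(scdesim)
g <- simulate_gene(calibration_default(),
                   design_spec(5, "POISSON", 50, fold_change = 2), seed = 7)
g
#> single_gene_dataset: 554 cells, 10 individuals, fold change 2, 40.1% zeros
run_de_methods(g)
#>             method  p_value statistic effect_estimate converged
#> 1     hurdle_fixed 5.47e-18    79.494          1.3102      TRUE
#> 2 hurdle_corrected 8.28e-01     0.376          0.0879      TRUE
#> 3     hurdle_mixed 3.91e-05    20.299          1.3153      TRUE
#> 4      tweedie_glm 2.08e-02     5.340          0.1665      TRUE
#> 5             gee1 5.96e-03     2.750          0.7371      TRUE
#> 6  pseudobulk_mean 1.24e-04     6.900          0.9136      TRUE
#> 7   pseudobulk_sum 9.23e-04     5.106          0.7025      TRUE
#> 8            tobit 1.25e-01     2.348          0.8402      TRUE
```

The naive hurdle is (deceptively) the most confident — the same test
that rejects half of all true nulls at this design. The random-effect
hurdle and the pseudo-bulk tests detect the effect with honest
calibration; the batch-corrected pipeline has destroyed the continuous
signal along with the donor effects.

The correlation diagnostic behind the hierarchy:

```r
m  <- simulate_matrix(calibration_default(),
                      design_spec(5, "POISSON", 25), 120, seed = 9)
correlation_diagnostic(m, n_draws = 200, seed = 10)
#> correlation_summary (113 genes): median intra 0.376 (IQR 0.116),
#>                                  median inter 0.311 (IQR 0.122)
```

Cells of the same donor correlate more than cells of different donors;
collapse the hierarchy (`f1 ≡ 0`) and the gap vanishes.

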