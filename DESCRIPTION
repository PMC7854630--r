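Package: scdesim
Title: Hierarchical Single-Cell Expression Simulation and
    Differential-Expression Benchmarking Under Pseudoreplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates hierarchical single-cell gene expression data
    (gamma-distributed grand means, linear inter-individual variance,
    logarithmic mean-dispersion relationship, gamma-distributed dropout)
    and benchmarks differential-expression procedures that do and do not
    account for the correlation of cells within an individual. Implements
    the two-part hurdle model with fixed and random-intercept variants,
    pseudo-bulk aggregation with a negative-binomial Wald test, Gaussian
    GEE1 with exchangeable working correlation, Tweedie and censored
    Gaussian (Tobit) regressions, and per-individual batch correction.
    Provides Monte-Carlo harnesses for type-1-error, power and rank-order
    evaluation, and intra- versus inter-individual Spearman correlation
    diagnostics on pruned gene sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    mgcv,
    survival,
    Matrix,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
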