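Package: KernelDCA
Title: Kernel-Based Differential Co-Expression Analysis of General Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests gene pathways for differential co-expression with respect to
    continuous, discrete, or categorical risk factors. Individual-specific gene
    correlations are estimated as cross products of standardized residuals after
    removing mean and variance effects of the risk factor, covariates, and batch
    variables (per-group variances or a double generalized linear model). A
    Hilbert-Schmidt independence criterion statistic relates cross-product
    similarity to risk-factor similarity under linear, projection, and Gaussian
    kernels; a row-permutation algorithm that preserves mean and variance
    effects yields empirical p-values, aggregated across kernels by Fisher's
    method. Includes an eigengene comparator, a large-sample weighted
    chi-square null, simulation engines for multivariate-normal pathways and
    negative-binomial RNA-seq counts, GMT gene-set handling, logCPM
    preprocessing, and an end-to-end study driver with BH false discovery rate
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    S4Vectors,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'adjust.R'
    'kernels.R'
    'inference.R'
    'analytic.R'
    'simulate.R'
    'pipeline.R'
    'studies.R'
    'KernelDCA-package.R'
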