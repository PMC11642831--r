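---
title: "Kernel-based differential co-expression analysis: models and methods"
author: "KernelDCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based differential co-expression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KernelDCA)
```

# The problem

Differential co-expression analysis (DCA) asks whether the *correlation*
structure among the genes of a pathway depends on a risk factor — age,
a mutation, an exposure — rather than whether mean expression does. A
pathway that co-regulates tightly in healthy tissue may lose (or re-wire)
that coordination under a risk factor, even when no single gene shifts in
mean. Classical pairwise tests handle only categorical group comparisons,
need multiple-testing corrections over all gene pairs, and are easily
fooled by two artifacts: batch effects, and *variance-specific* effects,
where a risk factor changes expression variance without touching
co-expression.

KernelDCA implements a kernel-association framework for this problem. It
handles continuous, discrete, or categorical risk factors (singly or
jointly), adjusts for covariates and batch variables, explicitly removes
variance effects, and calibrates inference by permutation so it is valid at
the modest sample sizes of real expression studies.

# The model and test statistic

For samples $j = 1, \dots, n$ and pathway genes $k = 1, \dots, r$, the
expression $Y_{jk}$ (on an approximately normal scale such as logCPM) is
residualized against an intercept, the risk factor(s) $X$, covariates $C$,
and batch variables $M$:

$$e_{jk} = Y_{jk} - \hat\beta_k X_j - C_{j\cdot}\hat\Gamma_{\cdot k}
          - M_{j\cdot}\hat\Phi_{\cdot k},$$

and standardized by an estimate of the conditional variance,
$\tilde e_{jk} = e_{jk} / s_{jk}$. Standardization is what prevents a
factor with variance-only effects from masquerading as differential
co-expression. Two variance estimators are provided:

* **per-group** (single categorical factor): the df-corrected sample
  variance of the residuals within each factor level, with the shared
  covariate parameters apportioned to groups by their sample share;
* **double GLM** (any design): a gamma GLM with log link fitted to the
  squared residuals on `[intercept | X]`, iterated with a reweighted
  least-squares mean fit until the coefficients move by less than `1e-6`
  (at most 20 outer iterations; non-convergence is flagged and the last
  iterate used). By default the variance model contains only the risk
  factor(s) — matching the generating model of the simulation study —
  with covariates/batch admitted via a flag.

The *individual-specific gene correlations* are the cross products of the
standardized residuals, one column per gene pair:

$$Z_{j\cdot} = (\tilde e_{j1}\tilde e_{j2},\; \tilde e_{j1}\tilde e_{j3},
\;\dots,\; \tilde e_{j,r-1}\tilde e_{jr}), \qquad q = r(r-1)/2.$$

Under the null hypothesis of no differential co-expression each cross
product is independent of the risk factor. Dependence is measured by the
Hilbert–Schmidt independence criterion: with an $n \times n$ similarity
matrix $K_Z$ over cross-product rows and $K_X = XX^\top$ over standardized
risk factors,

$$T = \frac{1}{n}\,\mathrm{tr}(K_Z K_X).$$

Three kernels are offered for $K_Z$ — **linear** ($ZZ^\top$, a scaled
covariance), **projection** ($UU^\top$ over the retained left singular
vectors, which equalizes the weight of every co-expression component), and
**Gaussian** ($\exp(-\nu\lVert Z_{j\cdot}-Z_{j'\cdot}\rVert^2)$) — because
the best kernel depends on the (unknown) pathway architecture: how sparse
the signal is, whether effect directions agree, and how the signal
distributes over the spectrum of $ZZ^\top$.

## Centering convention

The statistic is computed after mean-centering each cross-product column
and standardizing each risk-factor column (so $K_X$ has zero row sums).
Cross products have a nonzero baseline — their column means estimate the
baseline gene-pair correlations — and HSIC targets *dependence*, not
shared means; centering removes this common offset from the statistic
without affecting permutation validity. `center = FALSE` reproduces the
uncentered formula exactly. Risk-factor scaling makes the statistic
invariant to the units of each factor and puts mixed factor types on a
common footing.

## Gaussian bandwidth

`nu = 1e-4` is the default bandwidth on the squared-Euclidean distance
between cross-product rows. At this scale the Gaussian kernel is a gentle,
nearly affine transform of the linear kernel on typical pathway data
(distances of order $q$), which is why the two often perform similarly;
larger `nu` emphasizes local structure. The radial (distance) form is
used; an inner-product variant `exp(-nu (Z_j Z_{j'}^T)^2)` exists behind an
internal flag for comparison, the printed form of the kernel being
typographically ambiguous in parts of the literature.

# Permutation inference

Asymptotic theory for $T$ (a weighted sum of chi-squares) is unreliable at
expression-study sample sizes, and moment-matching approximations fail
here because the mean and variance effects of the risk factor are removed
before kernel construction. Inference is therefore by permutation:

1. Row-permute the standardized residuals, $\tilde e^{(b)} = H^{(b)}\tilde
   e$. Permuting whole rows preserves the gene-by-gene correlation matrix
   exactly while severing any link to the risk factor.
2. Reconstruct the null pathway
   $Y^{(b)}_{jk} = \hat\mu_{jk} + s_{jk}\tilde e^{(b)}_{jk}$, so the mean
   and variance effects of $X$, $C$, $M$ are preserved, recompute cross
   products, and form $T^{(b)}$ against the fixed $K_X$.
3. $p = \left(\sum_b 1\{T^{(b)} \ge T\} + 1\right)/(B+1)$, ties counted
   (conservative); the smallest attainable p-value is $1/(B+1)$.

**Refitting.** With `refit = TRUE` (default) each reconstructed pathway is
re-run through the full mean/variance adjustment, so estimation noise
propagates into the null exactly as it does into the observed statistic;
the resulting null p-values are close to uniform. `refit = FALSE` permutes
$\tilde e$ directly and exploits a useful identity: a row permutation
conjugates every kernel matrix ($K \mapsto PKP^\top$), so
$T^{(b)} = x_b^\top K x_b / n$ with $x_b$ the inverse-permuted risk scores
— orders of magnitude faster. Because the observed residuals are
orthogonal to the design while permuted ones are not, the fast mode is
*conservative* (null p-values pile up above 0.5); it never inflates the
type I error rate, and is the right tool for large null calibration
studies and screening. Power comparisons between methods are unaffected in
ordering because all methods share the same stream and the same
conservatism.

**Multi-kernel aggregation.** One shared permutation stream drives all
kernels. Per-kernel empirical p-values $p_d$ are combined by Fisher's
method, $T' = -2\sum_d \log p_d$, and $T'$ is itself calibrated against
the permutation null: each null statistic receives a pseudo-p-value by
self-inclusive $\ge$-ranking among the $B$ nulls (values in $[1/B, 1]$,
avoiding $\log 0$; the rank convention is a design choice, made
self-inclusive for numerical safety), and the combined p-value is the
empirical tail probability of $T'$ among the $T'^{(b)}$. A single-kernel
request short-circuits to that kernel's own empirical p-value.

**Eigengene comparator.** The standard eigengene approach tests only the
top left singular vector of the centered cross-product matrix; its
statistic here is the squared multiple correlation $R^2$ of that vector on
the standardized risk factors ($R^2$, the correlation, and the regression
F give the same permutation rejection region for one factor), calibrated
by the same permutation scheme. When signal lives in lower-variance
components — notably under mixed-sign (Positive/Negative) architectures —
the eigengene test loses most of its power while the kernel tests do not.

**Analytic null.** For large samples (`analyticPvalue()`, guarded with a
warning below $n = 1000$) the null is approximated by
$\sum_{ij} w_{ij}\chi^2_{1,ij}$ with $w_{ij} = \hat\lambda_{Z,i}
\hat\lambda_{X,j}/n^2$ over nonzero eigenvalues of the double-centered
kernels; the scaling makes $\sum w$ equal the exact permutation-null mean
$\mathrm{tr}(K_Z^c)\mathrm{tr}(K_X^c)/n^2$. Products below
$10^{-12}\times$ the maximum are dropped for stability. The tail
probability is computed by Imhof's integral (implemented in-package and
verified against the closed forms $w\chi^2_1$ and $\chi^2_2$). At
$n = 2000$ the analytic and permutation p-values agree to about two
decimals (rank correlation $> 0.99$ in the package's tests).

**Determinism.** All randomness flows from explicit seeds; per-pathway
seeds are derived from the master seed plus a polynomial hash of the
pathway label, so multi-worker runs and reordered dispatch reproduce
byte-identical results.

# What the simulators emulate

## Multivariate-normal pathway model

`simulateNormalPathway()` draws, per pathway: risk factor $X_j \sim$
Uniform(0, 2) (continuous) or Bernoulli(0.5) (categorical), covariate
$C_j \sim$ Uniform(0, 2), intercepts $\alpha_k \sim N(0,1)$, and imposes

$$E[Y_{jk}\mid X, C] = \alpha_k + X_j + C_j, \qquad
\log \mathrm{Var}(Y_{jk}\mid X, C) = 1 + \delta_k X_j, \qquad
\mathrm{Corr}(Y_{jk}, Y_{jk'}\mid X, C) = \rho_j + s_k s_{k'} \tau X_j$$

with $\rho_j \sim$ Uniform(0.25, 0.5), $\delta_k \sim$ Uniform(0, 0.1),
and $\tau \sim$ Uniform(0.1, 0.2) (or $\tau = 0$ under the null). The
third moment equation is realized *as a correlation* via a two-factor
construction (shared factors $A_j$, $B_j$ plus idiosyncratic noise): the
generating parameters are named "baseline correlation" and the 0.25–0.5
range is incompatible with covariances against variances of $e^1$ or
more, so the correlation reading is the only coherent one. Per-gene signs
$s_k$ (all $+1$ for 'Positive', random $\pm 1$ for 'Positive/Negative')
implement mixed directions while guaranteeing a valid positive
semidefinite correlation matrix, which arbitrary per-pair signs would
not. $\rho_j$ is per-individual as the subscript indicates, with
`fixedRho` available for a constant-correlation variant. Sparsity removes
a fraction of genes from the differential set. With three risk factors the
effective exposure $(2/3)\sum_l X_{jl}$ replaces $X_j$ in all three
moment equations.

## Negative-binomial genome model

`simulateNbDataset()` draws counts with
$\mu_{jk} = \alpha_k \exp(\beta_k X_j + \gamma_k C_j + \delta_k X_j
U_{jk})$, $U_{jk} \sim N(0,1)$ latent, $\alpha_k$ lognormal(meanlog 5.54,
sdlog 0.697) (median baseline ≈ 255 counts), $\beta_k, \gamma_k \sim
N(0, 0.01)$, $\delta_k \sim N(0, 6.25\times 10^{-4})$, and NB dispersion
$\phi = 0.25$ ($\mathrm{Var} = \mu + \phi\mu^2$), reflecting human bulk
RNA-seq. Expected means are rescaled per sample so totals match a library
size drawn from $\{2\times 10^6, 10^7\}$ — scaling the means rather than
thinning counts, which would distort the dispersion. The latent
interaction $X_j U_{jk}$ inflates variance in an $X$-dependent way but
creates no co-expression, so *every* pathway is null: this data set is the
stress test that separates variance effects from differential
co-expression. Counts enter the pipeline as $\log_2(\mathrm{count} + 1)$
(pseudocount 1, configurable; the canonical recipe does not fix one) with
log total counts as a fixed covariate.

Neither simulator attempts GC bias, batch structure beyond the modeled
variables, or single-cell dropout; passing tests demonstrate calibration
and power under the stated moment structures, not robustness to artifacts
outside them.

# Numerical choices and edge cases

* Mean fits share one QR decomposition across genes; the design is
  rank-checked and collinear columns are named in the error.
* Constant genes, missing values, fewer than 10 samples, and categorical
  levels with fewer than 3 samples are rejected at construction.
* Fitted variances below $10^{-12}$ are an error (degenerate gene); the
  gamma IRLS is converged on coefficients so zero squared residuals are
  harmless.
* Projection-kernel rank uses the conventional threshold
  $10^{-10}\max(n,q)$ relative to the top singular value.
* Per-group variance denominators are $n_g - p_g$ with $p_g = 1 +
  (\text{shared parameters})\cdot n_g/n$, unbiased under the group model.
* Empirical p-values live on the $1/(B+1)$ grid and never drop below
  $1/(B+1)$.
* Categorical risk factors are treatment-coded in sorted level order for
  reproducibility; the original labels drive per-group variances.

# Problem sizes used in the packaged experiments

The replicated experiments in the test suite and acceptance script use the
study's design points at desk scale, chosen once: 500 (normal-model) and
200 (NB-model) null pathways with $B = 200$ permutations in fast
permutation mode for type I error; 100 replicates at $B = 200$ for the
power ordering; $n = 50{,}000$ samples for simulator moment checks; and 50
pathways at $n = 2000$, $B = 2000$ for the analytic-vs-permutation
comparison. Type I error is judged against the nominal level plus three
binomial standard errors. For real studies, $B = 10{,}000$ permutations
with `refit = TRUE` is the recommended setting for FDR analyses.

# Known limitations

* The fast permutation mode is conservative (see above); use
  `refit = TRUE` when calibrated p-values matter.
* Latent batch effects must be supplied as columns of $M$; the package
  does not estimate surrogate variables, and confounding from unmodeled
  non-biological variation cannot be excluded.
* Variance adjustment relies on correct specification of the variance
  design; a misspecified variance model for a continuous factor can leak
  variance effects into the test. Rank-based transformations of
  expression induce exactly such effects and are discouraged.
* Pathways below 5 genes after intersection with the expression matrix
  are dropped by the study driver; cross products need at least 2 genes.

# A worked example

```{r example, eval = FALSE}
sim <- simulateNormalPathway(
  NormalSimConfig(n = 300, r = 10, riskType = "categorical",
                  architecture = "PositiveNegative", seed = 1))
res <- kdcaTest(sim$data, B = 1000, seed = 2, eigengene = TRUE)
res
```

The `KdcaResult` shows the per-kernel HSIC statistics and empirical
p-values, the Fisher statistic with its combined p-value, and the
eigengene p-value; see the README for a full run with printed output and a
study-level example over a GMT collection.
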