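# Small fixtures built in code.

# random pathway with a continuous risk factor and one covariate
randomPathway <- function(n = 20, r = 3, seed = 1, categorical = FALSE) {
  set.seed(seed)
  X <- if (categorical) factor(rbinom(n, 1, 0.5)) else runif(n, 0, 2)
  C <- runif(n, 0, 2)
  Xnum <- if (categorical) as.numeric(as.character(X)) else X
  Y <- matrix(rnorm(n * r), n, r) + Xnum + C
  PathwayData(Y, X, covariates = C)
}

# residual matrix with exactly mean-zero, unit-sample-variance columns
unitResiduals <- function(n = 30, r = 4, seed = 2) {
  set.seed(seed)
  m <- scale(matrix(rnorm(n * r), n, r))
  attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
  m
}
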