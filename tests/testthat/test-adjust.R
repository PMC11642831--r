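test_that("mean model recovers exact linear relations and matches the
           normal equations", {
  n <- 20
  set.seed(1)
  X <- runif(n, 0, 2)
  # one gene an exact multiple of X, one noisy gene to keep the object valid
  Y <- cbind(g1 = 2 * X, g2 = rnorm(n))
  pd <- PathwayData(Y, X)
  fit <- fitMeanModel(pd)
  expect_equal(unname(fit$coefs["X1", "g1"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefs["(Intercept)", "g1"]), 0, tolerance = 1e-10)
  expect_lt(max(abs(fit$e[, "g1"])), 1e-10)

  # random instance vs a brute-force normal-equations solve
  pd2 <- randomPathway(n = 20, r = 3, seed = 42)
  fit2 <- fitMeanModel(pd2)
  D <- fit2$design
  betaOracle <- solve(crossprod(D), crossprod(D, expressionMatrix(pd2)))
  eOracle <- expressionMatrix(pd2) - D %*% betaOracle
  expect_equal(unname(fit2$e), unname(eOracle), tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(D, fit2$e))), 1e-8)
})

test_that("degenerate inputs are rejected with informative errors", {
  n <- 20
  set.seed(2)
  X <- runif(n)
  expect_error(PathwayData(cbind(g1 = rep(5, n), g2 = rnorm(n)), X),
               "constant gene.*g1")
  expect_error(PathwayData(matrix(rnorm(2 * n), n), cbind(a = X, b = X)) |>
                 fitMeanModel(), "collinear.*b")
  Yna <- matrix(rnorm(2 * n), n); Yna[1] <- NA
  expect_error(PathwayData(Yna, X), "missing")
  expect_error(PathwayData(matrix(rnorm(10), 5), runif(5)), "10 samples")
  expect_error(PathwayData(matrix(rnorm(2 * n), n),
                           factor(c("a", rep("b", n - 1)))), ">= 3 samples")
})

test_that("per-group variance estimation recovers group variances and
           standardization gives unit within-group variance", {
  n <- 2000
  set.seed(3)
  g <- factor(rep(c("a", "b"), each = n / 2))
  sdv <- ifelse(g == "a", 1, 2)
  Y <- cbind(rnorm(n, sd = sdv), rnorm(n, sd = sdv), rnorm(n, sd = sdv))
  pd <- PathwayData(Y, g)
  fit <- fitMeanModel(pd)
  s2 <- estimateVariance(fit$e, pd, mode = "per-group")
  expect_equal(unname(s2[g == "a", 1][1]), 1, tolerance = 0.1)
  expect_equal(unname(s2[g == "b", 1][1]), 4, tolerance = 0.4)
  eStd <- standardizeResiduals(fit$e, s2)
  for (lev in levels(g)) {
    wv <- apply(eStd[g == lev, ], 2, var)
    expect_true(all(wv > 0.95 & wv < 1.05))
  }
})

test_that("double GLM recovers the generating log-variance model", {
  n <- 1000
  set.seed(4)
  X <- runif(n, 0, 2)
  # approximate SE of the gamma log-link slope: Var(theta) ~ 2 (D'D)^-1
  Dv <- cbind(1, X)
  se <- sqrt(2 * diag(solve(crossprod(Dv))))

  # homoskedastic: slope within 3 SE of zero
  Y0 <- cbind(rnorm(n), rnorm(n))
  pd0 <- PathwayData(Y0, X)
  s20 <- estimateVariance(fitMeanModel(pd0)$e, pd0, mode = "dglm")
  slope0 <- attr(s20, "varCoefs")[2, ]
  expect_true(all(abs(slope0) < 3 * se[2]))

  # log Var = 1 + 0.1 X: slope and intercept recovered within 3 SE
  Y1 <- cbind(rnorm(n, sd = exp((1 + 0.1 * X) / 2)),
              rnorm(n, sd = exp((1 + 0.1 * X) / 2)))
  pd1 <- PathwayData(Y1, X)
  s21 <- estimateVariance(fitMeanModel(pd1)$e, pd1, mode = "dglm")
  th <- attr(s21, "varCoefs")
  expect_true(all(abs(th[2, ] - 0.1) < 3 * se[2]))
  expect_true(all(abs(th[1, ] - 1) < 3 * se[1]))
  expect_true(all(attr(s21, "converged")))
})

test_that("standardization identities hold", {
  e <- matrix(0, 12, 3)
  s2 <- matrix(1, 12, 3)
  expect_identical(standardizeResiduals(e, s2), e)
  e2 <- matrix(rnorm(36), 12, 3)
  expect_identical(standardizeResiduals(e2, s2), e2)
  s2[1, 1] <- 0
  expect_error(standardizeResiduals(e2, s2), "strictly positive")
})

test_that("cross products enumerate gene pairs lexicographically", {
  eStd <- matrix(rnorm(30), 10, 3)
  cp <- crossProducts(eStd)
  expect_equal(ncol(crossProductMatrix(cp)), 3)
  expect_equal(unname(pairIndex(cp)),
               matrix(c(1L, 1L, 2L, 2L, 3L, 3L), ncol = 2))
  expect_equal(crossProductMatrix(cp)[, 1], eStd[, 1] * eStd[, 2])
  # a row of ones maps to a row of ones
  eStd[1, ] <- 1
  expect_equal(unname(crossProductMatrix(crossProducts(eStd))[1, ]),
               c(1, 1, 1))
  # q = r(r-1)/2
  expect_equal(ncol(crossProductMatrix(crossProducts(matrix(rnorm(200),
                                                            20, 10)))), 45)
  expect_error(crossProducts(matrix(rnorm(10), 10, 1)), "at least 2")
})

test_that("cross-product column means equal pairwise correlations up to the
           1/n variance-divisor factor", {
  n <- 30
  eStd <- unitResiduals(n = n, r = 4, seed = 9)
  cp <- crossProducts(eStd)
  cm <- colMeans(crossProductMatrix(cp))
  pr <- pairIndex(cp)
  expected <- cor(eStd)[pr] * (n - 1) / n
  expect_equal(unname(cm), unname(expected), tolerance = 1e-12)
})

test_that("row permutations leave the gene-by-gene correlation matrix
           unchanged", {
  set.seed(10)
  eStd <- matrix(rnorm(25 * 4), 25, 4)
  base <- cor(eStd)
  for (i in 1:5) {
    perm <- sample.int(25)
    expect_equal(cor(eStd[perm, ]), base, tolerance = 1e-12)
  }
})

test_that("standardizing removes variance-driven association between
           cross-product magnitude and the risk factor", {
  n <- 2000
  sim <- simulateNormalPathway(
    NormalSimConfig(n = n, r = 5, tauRange = NULL, deltaRange = c(0.3, 0.3),
                    seed = 11))
  adj <- adjustPathway(sim$data, varianceMode = "dglm")
  Z <- crossProductMatrix(crossProducts(adj))
  x <- riskFactors(sim$data)[, 1]
  mag <- rowMeans(abs(Z))
  fit <- summary(lm(mag ~ x))$coefficients
  expect_lt(abs(fit["x", "Estimate"]), 3 * fit["x", "Std. Error"])
})
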