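test_that("HSIC trace formula agrees with the elementwise double sum", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(64), 8, 8))
  B <- crossprod(matrix(rnorm(64), 8, 8))
  tracePath <- sum(diag(A %*% B)) / 8
  expect_equal(hsicStatistic(A, B), tracePath, tolerance = 1e-12)
  expect_equal(hsicStatistic(diag(8), diag(8)), 1)
  expect_equal(hsicStatistic(matrix(0, 8, 8), B), 0)
  expect_error(hsicStatistic(diag(3), diag(4)), "same size")
})

test_that("empirical p-value follows the (count + 1)/(B + 1) rule with ties
           counted", {
  expect_equal(empiricalPvalue(5, c(1, 2, 3, 4)), 1 / 5)
  expect_equal(empiricalPvalue(0, c(1, 2, 3, 4)), 1)
  expect_equal(empiricalPvalue(3, c(1, 2, 3, 4)), 3 / 5)  # tie counts
  # naive counting oracle on random draws
  set.seed(2)
  Tn <- rnorm(500); To <- 0.3
  expect_equal(empiricalPvalue(To, Tn),
               (sum(ifelse(Tn >= To, 1, 0)) + 1) / 501)
  # minimum attainable value at B = 10000
  expect_equal(empiricalPvalue(10, runif(10000)), 1 / 10001)
  expect_error(empiricalPvalue(1, numeric(0)), "at least one")
})

test_that("null pathway reconstruction is exact under the identity
           permutation and preserves gene-gene correlations", {
  pd <- randomPathway(n = 40, r = 4, seed = 3)
  adj <- adjustPathway(pd)
  idp <- permuteNullPathway(adj, pd, seq_len(40))
  expect_equal(expressionMatrix(idp), expressionMatrix(pd),
               tolerance = 1e-10)
  set.seed(4)
  perm <- sample.int(40)
  nullPd <- permuteNullPathway(adj, pd, perm)
  eStd <- standardizedResiduals(adj)
  expect_equal(cor(eStd[perm, ]), cor(eStd), tolerance = 1e-12)
  expect_error(permuteNullPathway(adj, pd, c(1, 1, 3:40)), "permutation")
})

test_that("permutation destroys the co-expression signal in a differential
           pathway", {
  sim <- simulateNormalPathway(
    NormalSimConfig(n = 300, r = 6, tauRange = c(0.2, 0.2), fixedRho = 0.3,
                    architecture = "Positive", seed = 5))
  res <- kdcaTest(sim$data, kernels = "linear", B = 100, seed = 6,
                  refit = FALSE)
  # observed dependence well into the right tail of the permutation null
  expect_gt(kernelStats(res)[["linear"]], mean(nullStats(res)))
  expect_lte(unname(kernelPvalues(res)[["linear"]]), 0.05)
})

test_that("fast-path null statistics equal explicitly rebuilt kernels on the
           permuted residuals", {
  pd <- randomPathway(n = 30, r = 4, seed = 7)
  res <- kdcaTest(pd, B = 3, seed = 11, refit = FALSE)
  adj <- adjustPathway(pd)
  eStd <- standardizedResiduals(adj)
  KX <- riskKernel(riskFactors(pd))
  set.seed(11)
  for (b in 1:3) {
    perm <- sample.int(30)
    Zb <- crossProductMatrix(crossProducts(eStd[perm, ]))
    for (k in c("linear", "projection", "gaussian")) {
      Kb <- switch(k, linear = linearKernel(Zb),
                   projection = projectionKernel(Zb),
                   gaussian = gaussianKernel(Zb))
      expect_equal(unname(nullStats(res)[b, k]), hsicStatistic(Kb, KX),
                   tolerance = 1e-10)
    }
  }
})

test_that("identical seeds give bit-identical results in both permutation
           modes", {
  pd <- randomPathway(n = 30, r = 3, seed = 8)
  a <- kdcaTest(pd, B = 25, seed = 99, refit = FALSE, eigengene = TRUE)
  b <- kdcaTest(pd, B = 25, seed = 99, refit = FALSE, eigengene = TRUE)
  expect_identical(nullStats(a), nullStats(b))
  expect_identical(combinedPvalue(a), combinedPvalue(b))
  expect_identical(eigengenePvalue(a), eigengenePvalue(b))
  a2 <- kdcaTest(pd, B = 10, seed = 99, refit = TRUE)
  b2 <- kdcaTest(pd, B = 10, seed = 99, refit = TRUE)
  expect_identical(nullStats(a2), nullStats(b2))
})

test_that("Fisher combination is coherent: single kernel reduces to its own
           empirical p-value and the statistic matches -2 sum log p", {
  pd <- randomPathway(n = 30, r = 3, seed = 9)
  one <- kdcaTest(pd, kernels = "linear", B = 50, seed = 1, refit = FALSE)
  expect_equal(combinedPvalue(one), unname(kernelPvalues(one)[["linear"]]))
  all3 <- kdcaTest(pd, B = 50, seed = 1, refit = FALSE)
  expect_equal(all3@statFisher, -2 * sum(log(kernelPvalues(all3))),
               tolerance = 1e-12)
})

test_that("empirical p-values respect the 1/(B+1) lower bound and the
           1/(B+1) grid", {
  for (seed in 1:4) {
    pd <- randomPathway(n = 25, r = 3, seed = seed)
    res <- kdcaTest(pd, B = 19, seed = seed, refit = FALSE,
                    eigengene = TRUE)
    pv <- c(kernelPvalues(res), combinedPvalue(res), eigengenePvalue(res))
    expect_true(all(pv >= 1 / 20 - 1e-12))
    expect_true(all(pv <= 1 + 1e-12))
    expect_equal(pv * 20, round(pv * 20), tolerance = 1e-9)
  }
})

test_that("eigengene statistic is the squared multiple correlation and
           detects a perfectly aligned top component", {
  set.seed(10)
  x <- rnorm(50)
  qrX <- qr(cbind(1, x))
  expect_equal(KernelDCA:::rsquared(2 * x + 3, qrX), 1, tolerance = 1e-12)
  y <- rnorm(50)
  r2 <- KernelDCA:::rsquared(y, qrX)
  expect_equal(r2, summary(lm(y ~ x))$r.squared, tolerance = 1e-12)

  # strong shared signal: eigengene p-value is small for a Positive
  # architecture where the top component carries the signal
  sim <- simulateNormalPathway(
    NormalSimConfig(n = 200, r = 6, tauRange = c(0.2, 0.2),
                    architecture = "Positive", seed = 12))
  eg <- eigengeneTest(sim$data, B = 99, seed = 13, refit = FALSE)
  expect_lt(eg$p.value, 0.1)
})

test_that("weighted chi-square tail matches closed forms and the analytic
           p-value validates kernel PSD-ness", {
  w <- 0.37
  expect_equal(weightedChisqTail(w, w), pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(weightedChisqTail(2 * w, c(w, w)), exp(-1), tolerance = 1e-6)
  # three-weight case against a Monte Carlo oracle
  set.seed(14)
  ws <- c(2, 1, 0.5)
  qs <- 4
  mc <- mean(colSums(ws * matrix(rchisq(3 * 2e5, 1), 3)) > qs)
  expect_equal(weightedChisqTail(qs, ws), mc, tolerance = 0.01)
  expect_error(weightedChisqTail(1, c(1, -1)), "nonnegative")
  notPsd <- diag(c(1, 1, -1))
  expect_error(suppressWarnings(analyticPvalue(notPsd, diag(3), 1)),
               "positive semidefinite")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  p <- c(0.01, 0.02, 0.03, 0.9)
  q <- bhFdr(p)
  expect_equal(q, c(0.04, 0.04, 0.04, 0.9))
  expect_true(all(q[1:3] <= 0.05) && q[4] > 0.05)
  expect_equal(bhFdr(0.2), 0.2)
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})
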