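test_that("normal simulator realizes the stated mean, variance and
           correlation moments", {
  n <- 20000
  sim <- simulateNormalPathway(
    NormalSimConfig(n = n, r = 4, riskType = "categorical",
                    tauRange = NULL, deltaRange = c(0.1, 0.1),
                    fixedRho = 0.4, seed = 1))
  Y <- expressionMatrix(sim$data)
  x <- as.numeric(as.character(sim$data@groups))
  C <- sim$data@covar[, 1]
  al <- sim$truth$alpha
  # mean: alpha_k + X + C
  resid <- Y - outer(rep(1, n), al) - x - C
  expect_lt(max(abs(colMeans(resid))), 0.05)  # ~4 SE at n = 20000
  # variance: exp(1) at X = 0, exp(1 + delta) at X = 1
  v0 <- apply(resid[x == 0, ], 2, var)
  v1 <- apply(resid[x == 1, ], 2, var)
  expect_equal(unname(v0), rep(exp(1), 4), tolerance = 0.05)
  expect_equal(unname(v1), rep(exp(1.1), 4), tolerance = 0.05)
  # null correlation equals rho regardless of X
  c0 <- cor(resid[x == 0, ])[lower.tri(diag(4))]
  c1 <- cor(resid[x == 1, ])[lower.tri(diag(4))]
  expect_equal(unname(c0), rep(0.4, 6), tolerance = 0.05)
  expect_equal(unname(c1), rep(0.4, 6), tolerance = 0.05)
})

test_that("differential pathways carry a correlation effect of size tau in
           the direction of the sign assignments", {
  n <- 20000
  sim <- simulateNormalPathway(
    NormalSimConfig(n = n, r = 4, riskType = "categorical",
                    tauRange = c(0.15, 0.15), deltaRange = c(0, 0),
                    fixedRho = 0.3, architecture = "Positive", seed = 2))
  Y <- expressionMatrix(sim$data)
  x <- as.numeric(as.character(sim$data@groups))
  c01 <- cor(Y[x == 0, 1] - sim$data@covar[x == 0, 1],
             Y[x == 0, 2] - sim$data@covar[x == 0, 1])
  c11 <- cor(Y[x == 1, 1] - sim$data@covar[x == 1, 1],
             Y[x == 1, 2] - sim$data@covar[x == 1, 1])
  expect_lt(abs((c11 - c01) - 0.15), 0.03)

  # continuous X: cross-product columns regress on X with positive slope
  sim2 <- simulateNormalPathway(
    NormalSimConfig(n = 5000, r = 4, riskType = "continuous",
                    tauRange = c(0.15, 0.15), deltaRange = c(0, 0),
                    architecture = "Positive", seed = 3))
  adj <- adjustPathway(sim2$data, varianceMode = "none")
  Z <- crossProductMatrix(crossProducts(standardizedResiduals(adj)))
  x2 <- riskFactors(sim2$data)[, 1]
  slopes <- apply(Z, 2, function(z) coef(lm(z ~ x2))[2])
  expect_true(all(slopes > 0))
})

test_that("invalid correlation configurations are rejected", {
  expect_error(NormalSimConfig(tauRange = c(0.3, 0.3), rhoRange = c(0.5, 0.6)),
               "exceeds 1")
})

test_that("negative-binomial simulator matches its count-model targets", {
  cfg <- NbSimConfig(nGenes = 400, n = 150, seed = 4)
  sim <- simulateNbDataset(cfg)
  # sample totals concentrate near the drawn library sizes
  totals <- rowSums(sim$counts)
  expect_true(all(abs(totals / sim$librarySizes - 1) < 0.2))
  expect_setequal(unique(sim$librarySizes), c(2e6, 1e7))

  # delta = beta = 0: per-gene mean proportional to alpha
  cfg0 <- NbSimConfig(nGenes = 300, n = 400, betaSd = 1e-12,
                      gammaSd = 1e-12, deltaSd = 1e-12,
                      librarySizes = 2e6, seed = 5)
  sim0 <- simulateNbDataset(cfg0)
  m <- colMeans(sim0$counts)
  # per-gene mean proportional to alpha (common library scaling)
  expect_gt(cor(log(m + 0.5), log(sim0$params$alpha)), 0.99)
  ratio <- m / sim0$params$alpha
  expect_lt(sd(ratio) / mean(ratio), 0.1)

  # method-of-moments dispersion on high-mean genes ~ 0.25
  hi <- which(colMeans(sim0$counts) > 200)
  mom <- vapply(hi, function(k) {
    x <- sim0$counts[, k]
    (var(x) - mean(x)) / mean(x)^2
  }, 0)
  expect_equal(median(mom), 0.25, tolerance = 0.025)
})

test_that("log transform and library covariate follow the stated recipe", {
  cts <- matrix(c(0, 1023, 3, 7), 2, 2)
  lt <- logTransformCounts(cts)
  expect_equal(lt$expression[1, 1], 0)
  expect_equal(lt$expression[2, 1], 10)
  expect_equal(lt$logLibSize, log(rowSums(cts)))
  expect_error(logTransformCounts(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("simulators are deterministic under a fixed seed", {
  a <- simulateNormalPathway(NormalSimConfig(n = 50, r = 3, seed = 6))
  b <- simulateNormalPathway(NormalSimConfig(n = 50, r = 3, seed = 6))
  expect_identical(expressionMatrix(a$data), expressionMatrix(b$data))
  expect_identical(a$truth, b$truth)
  na <- simulateNbDataset(NbSimConfig(nGenes = 50, n = 30, seed = 7))
  nb <- simulateNbDataset(NbSimConfig(nGenes = 50, n = 30, seed = 7))
  expect_identical(na$counts, nb$counts)
})
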