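## Replicated simulation experiments: type I error under the two null
## models, and power comparison across kernels and the eigengene approach.

#' Type I error study under the multivariate-normal pathway model
#'
#' Simulates independent null pathways (tau = 0: variance effects retained,
#' no correlation effect) and runs the combined-kernel test on each,
#' returning the combined p-values and the rejection rate at \code{level}.
#'
#' @param nPathways number of replicate pathways.
#' @param n,r sample and pathway size.
#' @param riskType risk factor type, see [NormalSimConfig()].
#' @param deltaRange variance-effect range (default c(0, 0.1)).
#' @param B permutations per pathway.
#' @param seed master seed; per-pathway seeds are derived from it.
#' @param refit see [kdcaTest()].
#' @param kernels kernels to combine.
#' @param varianceMode variance mode ("auto" resolves per risk type;
#'   \code{"none"} gives the deliberately unstandardized variant).
#' @param level nominal significance threshold (default 0.05).
#' @param eigengene also collect eigengene p-values.
#' @return list with \code{pvalues}, \code{pEigengene} (optional),
#'   \code{rejectionRate}, \code{level}, \code{nPathways}.
#' @export
typeINormalStudy <- function(nPathways = 500L, n = 300L, r = 10L,
                             riskType = "continuous",
                             deltaRange = c(0, 0.1), B = 200L, seed = 1L,
                             refit = FALSE,
                             kernels = c("linear", "projection", "gaussian"),
                             varianceMode = "auto", level = 0.05,
                             eigengene = FALSE) {
  p <- numeric(nPathways)
  pe <- if (eigengene) numeric(nPathways) else NULL
  for (i in seq_len(nPathways)) {
    simSeed <- deriveSeed(seed, paste0("normal-null-", i))
    sim <- simulateNormalPathway(
      NormalSimConfig(n = n, r = r, riskType = riskType, tauRange = NULL,
                      deltaRange = deltaRange, seed = simSeed))
    res <- kdcaTest(sim$data, kernels = kernels, B = B,
                    seed = deriveSeed(seed, paste0("test-", i)),
                    refit = refit, varianceMode = varianceMode,
                    eigengene = eigengene)
    p[i] <- res@pCombined
    if (eigengene) pe[i] <- res@pEigengene
  }
  list(pvalues = p, pEigengene = pe, rejectionRate = mean(p <= level),
       level = level, nPathways = nPathways)
}

#' Type I error study under the negative-binomial genome model
#'
#' Simulates a count data set with latent variance interactions, applies the
#' log2 transform with log library size as a fixed covariate, partitions
#' genes into pathways, and runs the combined-kernel test on each pathway.
#'
#' @param nGenes total genes simulated.
#' @param n samples.
#' @param pathwaySize genes per pathway.
#' @param riskType risk factor type.
#' @param B,seed,refit,kernels,level as in [typeINormalStudy()].
#' @param maxPathways optional cap on the number of pathways tested.
#' @return list with \code{pvalues}, \code{rejectionRate}, \code{level},
#'   \code{nPathways}.
#' @export
typeINbStudy <- function(nGenes = 2000L, n = 300L, pathwaySize = 10L,
                         riskType = "continuous", B = 200L, seed = 1L,
                         refit = FALSE,
                         kernels = c("linear", "projection", "gaussian"),
                         level = 0.05, maxPathways = NULL) {
  cfg <- NbSimConfig(nGenes = nGenes, n = n, pathwaySize = pathwaySize,
                     riskType = riskType,
                     seed = deriveSeed(seed, "nb-dataset"))
  sim <- simulateNbDataset(cfg)
  lt <- logTransformCounts(sim$counts)
  pathways <- sim$pathways
  if (!is.null(maxPathways) && length(pathways) > maxPathways)
    pathways <- pathways[seq_len(maxPathways)]
  p <- numeric(length(pathways))
  for (i in seq_along(pathways)) {
    idx <- pathways[[i]]
    pd <- PathwayData(lt$expression[, idx, drop = FALSE], sim$X,
                      covariates = cbind(C = sim$C,
                                         logLib = lt$logLibSize))
    res <- kdcaTest(pd, kernels = kernels, B = B,
                    seed = deriveSeed(seed, names(pathways)[i]),
                    refit = refit, varianceMode = "dglm")
    p[i] <- res@pCombined
  }
  list(pvalues = p, rejectionRate = mean(p <= level), level = level,
       nPathways = length(pathways))
}

#' Power study across kernels and the eigengene comparator
#'
#' Simulates differentially co-expressed pathways and estimates the power of
#' each single-kernel test, the Fisher-combined test, and the eigengene
#' comparator at \code{level}, all on shared permutation streams.
#'
#' @param nReplicates replicate pathways.
#' @param n,r,riskType,sparsity,architecture,tauRange see
#'   [NormalSimConfig()].
#' @param B,seed,refit,kernels,level as in [typeINormalStudy()].
#' @return list with per-method power estimates and the p-value matrix.
#' @export
powerStudy <- function(nReplicates = 100L, n = 300L, r = 10L,
                       riskType = "categorical", sparsity = 0,
                       architecture = "PositiveNegative",
                       tauRange = c(0.1, 0.2), B = 200L, seed = 1L,
                       refit = FALSE,
                       kernels = c("linear", "projection", "gaussian"),
                       level = 0.05) {
  methods <- c(kernels, "combined", "eigengene")
  P <- matrix(NA_real_, nReplicates, length(methods),
              dimnames = list(NULL, methods))
  for (i in seq_len(nReplicates)) {
    sim <- simulateNormalPathway(
      NormalSimConfig(n = n, r = r, riskType = riskType, sparsity = sparsity,
                      architecture = architecture, tauRange = tauRange,
                      seed = deriveSeed(seed, paste0("power-sim-", i))))
    res <- kdcaTest(sim$data, kernels = kernels, B = B,
                    seed = deriveSeed(seed, paste0("power-test-", i)),
                    refit = refit, eigengene = TRUE)
    P[i, kernels] <- res@pKernel[kernels]
    P[i, "combined"] <- res@pCombined
    P[i, "eigengene"] <- res@pEigengene
  }
  power <- colMeans(P <= level)
  list(power = power, pvalues = P, level = level,
       nReplicates = nReplicates)
}
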