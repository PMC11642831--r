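## HSIC statistic, permutation null, per-kernel empirical p-values, Fisher
## multi-kernel aggregation, and the eigengene comparator.

#' Hilbert-Schmidt independence criterion statistic
#'
#' \eqn{T = \mathrm{tr}(K_Z K_X) / n}, computed as the elementwise sum
#' \eqn{\sum_{jj'} K_Z[j,j'] K_X[j,j'] / n} (the trace identity for
#' symmetric matrices). Large values indicate dependence between the two
#' similarity structures.
#'
#' @param KZ,KX n x n symmetric similarity matrices.
#' @return scalar statistic.
#' @export
hsicStatistic <- function(KZ, KX) {
  if (!identical(dim(KZ), dim(KX)) || nrow(KZ) != ncol(KZ))
    stop("KZ and KX must be square matrices of the same size")
  sum(KZ * KX) / nrow(KZ)
}

#' Empirical permutation p-value
#'
#' \eqn{p = (\#\{b : T^{(b)} \ge T\} + 1) / (B + 1)}; ties count toward the
#' numerator, so the smallest attainable value is \eqn{1/(B+1)}.
#'
#' @param Tobs observed statistic.
#' @param Tnull numeric vector of B null statistics.
#' @return empirical p-value in \[1/(B+1), 1\].
#' @export
empiricalPvalue <- function(Tobs, Tnull) {
  B <- length(Tnull)
  if (B < 1L) stop("need at least one null statistic")
  (sum(Tnull >= Tobs) + 1) / (B + 1)
}

#' Reconstruct a null pathway from a permutation of the residuals
#'
#' Applies one row permutation to the standardized residuals and rebuilds
#' the expression matrix from the fitted means and conditional standard
#' deviations: \eqn{Y^{(b)}_{jk} = \hat\mu_{jk} + s_{jk}\tilde e^{(b)}_{jk}}.
#' Row-wise permutation preserves the gene-by-gene correlations while
#' breaking any association between the risk factor and the co-expression
#' structure; the mean and variance effects of the risk factor, covariates
#' and batch variables are preserved by construction.
#'
#' @param adj an [AdjustedResiduals-class] object.
#' @param data the [PathwayData-class] it was fitted on.
#' @param perm integer permutation of \code{1:n}.
#' @return A [PathwayData-class] with the reconstructed expression.
#' @export
permuteNullPathway <- function(adj, data, perm) {
  stopifnot(is(adj, "AdjustedResiduals"), is(data, "PathwayData"))
  n <- nrow(adj@eStd)
  if (!identical(sort(perm), seq_len(n)))
    stop("perm must be a permutation of 1..n")
  Yb <- adj@fitted + sqrt(adj@s2) * adj@eStd[perm, , drop = FALSE]
  out <- data
  out@Y <- Yb
  out
}

## squared multiple correlation of y on the design qrX (intercept included)
rsquared <- function(y, qrX) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(0)
  1 - sum(qr.resid(qrX, y)^2) / tss
}

## top left singular vector of a (centered) matrix
topLeftSingular <- function(M) {
  svd(M, nu = 1L, nv = 0L)$u[, 1L]
}

## Core permutation engine shared by kdcaTest and eigengeneTest.
kdcaEngine <- function(data, kernels, B, seed, refit, varianceMode,
                       nu, center, eigengene, includeCovariatesInVariance) {
  if (varianceMode == "auto")
    varianceMode <- if (!is.null(data@groups)) "per-group" else "dglm"
  D <- designMatrix(data)
  Dv <- varianceDesign(data, includeCovariatesInVariance)
  qrD <- qr(D)
  qrDv <- qr(Dv)
  adj <- adjustMatrix(data@Y, D, Dv, data@groups, varianceMode, qrD, qrDv)
  n <- nrow(data@Y)
  pairs <- genePairs(ncol(data@Y))
  makeZ <- function(eStd) {
    Z <- eStd[, pairs[, 1L], drop = FALSE] * eStd[, pairs[, 2L], drop = FALSE]
    if (center) centerColumns(Z) else Z
  }
  Zc <- makeZ(adj$eStd)
  Xs <- riskScores(data@X)
  KX <- tcrossprod(Xs)
  nk <- length(kernels)

  Ks <- if (nk) buildKernels(Zc, kernels, nu = nu, center = FALSE) else list()
  Tobs <- vapply(Ks, function(K) hsicStatistic(K, KX), 0)
  if (nk && any(!is.finite(Tobs)))
    stop("non-finite observed statistic for kernel(s): ",
         paste(kernels[!is.finite(Tobs)], collapse = ", "))

  qrX <- if (eigengene) qr(cbind(1, Xs)) else NULL
  if (eigengene) {
    u <- topLeftSingular(Zc)
    egObs <- rsquared(u, qrX)
  }

  Tnull <- matrix(NA_real_, B, nk, dimnames = list(NULL, kernels))
  egNull <- if (eigengene) numeric(B) else NULL

  ## precompute factors for the fast (no-refit) path
  if (!refit && nk) {
    Uproj <- if ("projection" %in% kernels) {
      sv <- svd(Zc, nu = min(dim(Zc)), nv = 0L)
      keep <- sv$d > 1e-10 * max(dim(Zc)) * sv$d[1L]
      sv$u[, keep, drop = FALSE]
    } else NULL
    Kg <- Ks[["gaussian"]]
  }

  withSeed(seed, {
    ip <- integer(n)
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      if (refit) {
        Yb <- adj$fitted + sqrt(adj$s2) * adj$eStd[perm, , drop = FALSE]
        adjb <- adjustMatrix(Yb, D, Dv, data@groups, varianceMode, qrD, qrDv,
                             warnNonconverged = FALSE)
        Zb <- makeZ(adjb$eStd)
        if (nk) {
          Ksb <- buildKernels(Zb, kernels, nu = nu, center = FALSE)
          for (d in seq_len(nk))
            Tnull[b, d] <- hsicStatistic(Ksb[[d]], KX)
        }
        if (eigengene)
          egNull[b] <- rsquared(topLeftSingular(Zb), qrX)
      } else {
        ## row permutation of Z conjugates every kernel matrix, so the null
        ## statistic is x_b' K x_b / n with x_b the inverse-permuted risk
        ## scores; linear/projection reduce further to their factors.
        ip[perm] <- seq_len(n)
        xb <- Xs[ip, , drop = FALSE]
        for (d in seq_len(nk)) {
          Tnull[b, d] <- switch(kernels[d],
            linear = sum(crossprod(Zc, xb)^2) / n,
            projection = sum(crossprod(Uproj, xb)^2) / n,
            gaussian = sum(xb * (Kg %*% xb)) / n)
        }
        if (eigengene)
          egNull[b] <- rsquared(u[perm], qrX)
      }
    }
  })

  pKernel <- setNames(numeric(nk), kernels)
  for (d in seq_len(nk))
    pKernel[d] <- empiricalPvalue(Tobs[d], Tnull[, d])

  if (nk > 1L) {
    Tfisher <- -2 * sum(log(pKernel))
    ## null pseudo-p-values: self-inclusive ">=" rank among the B nulls
    pNull <- matrix(NA_real_, B, nk)
    for (d in seq_len(nk))
      pNull[, d] <- countGreaterEqual(Tnull[, d], Tnull[, d]) / B
    TfisherNull <- -2 * rowSums(log(pNull))
    pCombined <- empiricalPvalue(Tfisher, TfisherNull)
  } else if (nk == 1L) {
    Tfisher <- -2 * log(pKernel)
    pCombined <- unname(pKernel)
  } else {
    Tfisher <- NA_real_
    pCombined <- NA_real_
  }

  pEigengene <- if (eigengene) empiricalPvalue(egObs, egNull) else NA_real_

  list(Tobs = Tobs, Tnull = Tnull, pKernel = pKernel,
       Tfisher = unname(Tfisher), pCombined = pCombined,
       pEigengene = pEigengene,
       egObs = if (eigengene) egObs else NA_real_,
       egNull = egNull, varianceMode = varianceMode)
}

#' Kernel-based differential co-expression test (KDCA)
#'
#' Tests whether the individual-specific gene correlations of a pathway
#' (cross products of standardized residuals) are independent of the risk
#' factor(s). For each requested kernel the HSIC statistic
#' \eqn{T = \mathrm{tr}(K_Z K_X)/n} is compared against a permutation null
#' that row-permutes the standardized residuals and reconstructs the pathway
#' with its mean and variance effects intact. One shared permutation stream
#' drives all kernels; per-kernel empirical p-values are aggregated by
#' Fisher's method, \eqn{T' = -2\sum_d \log p_d}, itself calibrated against
#' the permutation null.
#'
#' With \code{refit = TRUE} (default) each permuted pathway is re-run
#' through the full mean/variance adjustment so estimation noise propagates
#' into the null; \code{refit = FALSE} permutes the standardized residuals
#' directly, which is much faster and exploits the permutation-equivariance
#' of all three kernels.
#'
#' @param data a [PathwayData-class] object.
#' @param kernels subset of \code{c("linear", "projection", "gaussian")}.
#' @param B number of permutations (>= 100 recommended).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param refit re-run the full adjustment on each reconstructed null
#'   pathway (see Details).
#' @param varianceMode variance estimation mode, see [adjustPathway()].
#' @param nu Gaussian kernel bandwidth.
#' @param center mean-center cross-product columns before kernel
#'   construction (recommended).
#' @param eigengene also run the eigengene comparator on the shared
#'   permutation stream.
#' @param includeCovariatesInVariance see [estimateVariance()].
#' @return A [KdcaResult-class] object.
#' @examples
#' sim <- simulateNormalPathway(NormalSimConfig(n = 100, r = 5, seed = 7))
#' res <- kdcaTest(sim$data, B = 99, seed = 1, refit = FALSE)
#' res
#' @export
kdcaTest <- function(data,
                     kernels = c("linear", "projection", "gaussian"),
                     B = 1000L, seed = NULL, refit = TRUE,
                     varianceMode = c("auto", "dglm", "per-group", "none"),
                     nu = 1e-4, center = TRUE, eigengene = FALSE,
                     includeCovariatesInVariance = FALSE) {
  varianceMode <- match.arg(varianceMode)
  kernels <- match.arg(kernels, several.ok = TRUE)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  eng <- kdcaEngine(data, kernels, B, seed, refit, varianceMode, nu, center,
                    eigengene, includeCovariatesInVariance)
  new("KdcaResult",
      statObs = eng$Tobs, statNull = eng$Tnull, pKernel = eng$pKernel,
      statFisher = eng$Tfisher, pCombined = eng$pCombined,
      pEigengene = eng$pEigengene, B = B,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      kernels = kernels, refit = refit, varianceMode = eng$varianceMode)
}

#' Eigengene comparator test
#'
#' The standard eigengene approach tests the top left singular vector of
#' the (column-centered) cross-product matrix: the observed statistic is the
#' squared multiple correlation from regressing that vector on the
#' standardized risk factor(s), calibrated by the same permutation algorithm
#' as [kdcaTest()].
#'
#' @inheritParams kdcaTest
#' @return list with \code{statistic} (observed R^2), \code{p.value},
#'   \code{statNull}, and \code{B}.
#' @export
eigengeneTest <- function(data, B = 1000L, seed = NULL, refit = TRUE,
                          varianceMode = c("auto", "dglm", "per-group",
                                           "none"),
                          center = TRUE,
                          includeCovariatesInVariance = FALSE) {
  varianceMode <- match.arg(varianceMode)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  eng <- kdcaEngine(data, character(0), B, seed, refit, varianceMode,
                    nu = 1e-4, center = center, eigengene = TRUE,
                    includeCovariatesInVariance = includeCovariatesInVariance)
  list(statistic = eng$egObs, p.value = eng$pEigengene,
       statNull = eng$egNull, B = B)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input validation
#' for p-values in (0, 1].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return vector of BH-adjusted q-values.
#' @export
bhFdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
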