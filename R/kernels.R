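## Similarity kernels for the cross products (linear, projection, Gaussian)
## and the risk factor (linear on standardized columns).
##
## Cross-product columns are mean-centered before kernel construction by
## default: the independence statistic targets dependence between views, not
## their shared nonzero baselines (cross products have mean equal to the
## baseline gene-pair correlation). Centering can be disabled for an exact
## uncentered-formula variant.

#' Linear kernel of the cross products
#'
#' \eqn{K_Z = Z Z^T} (a scaled covariance) after optional column centering.
#'
#' @param Z n x q cross-product matrix or a [CrossProducts-class] object.
#' @param center mean-center columns of Z first (default TRUE).
#' @return n x n symmetric positive semidefinite matrix.
#' @export
linearKernel <- function(Z, center = TRUE) {
  Z <- asCrossMatrix(Z, center)
  tcrossprod(Z)
}

#' Projection kernel of the cross products
#'
#' \eqn{K_Z = U U^T} over the left singular vectors of (centered) Z whose
#' singular values exceed \code{tol} times the largest; the kernel is the
#' orthogonal projector onto the retained column space, so
#' \code{trace(K_Z)} equals the retained rank and \eqn{K_Z^2 = K_Z}.
#'
#' @inheritParams linearKernel
#' @param tol relative singular-value tolerance; default
#'   \code{1e-10 * max(dim(Z))} mirrors standard numerical-rank conventions.
#' @export
projectionKernel <- function(Z, center = TRUE, tol = NULL) {
  Z <- asCrossMatrix(Z, center)
  if (is.null(tol)) tol <- 1e-10 * max(dim(Z))
  sv <- svd(Z, nu = min(dim(Z)), nv = 0L)
  keep <- sv$d > tol * sv$d[1L]
  if (!any(keep) || sv$d[1L] == 0)
    stop("degenerate cross-products: all singular values below tolerance")
  U <- sv$u[, keep, drop = FALSE]
  tcrossprod(U)
}

#' Gaussian kernel of the cross products
#'
#' \eqn{K_Z[j, j'] = \exp(-\nu \, \lVert Z_{j\cdot} - Z_{j'\cdot}\rVert^2)}
#' (squared Euclidean distance between cross-product rows); unit diagonal.
#' The default bandwidth \eqn{\nu = 10^{-4}} performs well across pathway
#' architectures at these data scales.
#'
#' @inheritParams linearKernel
#' @param nu nonnegative bandwidth (default 1e-4).
#' @export
gaussianKernel <- function(Z, nu = 1e-4, center = TRUE) {
  if (nu < 0) stop("nu must be nonnegative")
  Z <- asCrossMatrix(Z, center)
  G <- tcrossprod(Z)
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-nu * d2)
  diag(K) <- 1
  K
}

## inner-product Gaussian variant exp(-nu (Z_j Z_j'^T)^2); kept behind a flag
gaussianInnerKernel <- function(Z, nu = 1e-4, center = TRUE) {
  if (nu < 0) stop("nu must be nonnegative")
  Z <- asCrossMatrix(Z, center)
  exp(-nu * tcrossprod(Z)^2)
}

#' Linear kernel of the risk factor(s)
#'
#' Each risk-factor column is centered and scaled to unit variance, then
#' \eqn{K_X = X X^T} (summing over columns for multiple factors). Scaling
#' makes the statistic invariant to the units of each factor and puts mixed
#' factor types on a common footing.
#'
#' @param X numeric n x L matrix or vector (categorical factors pre-encoded).
#' @return n x n symmetric matrix with zero row sums.
#' @export
riskKernel <- function(X) {
  X <- as.matrix(X)
  Xs <- standardizeColumns(X, "risk-factor column")
  tcrossprod(Xs)
}

## standardized risk-factor columns (used by the fast permutation path)
riskScores <- function(X) {
  standardizeColumns(as.matrix(X), "risk-factor column")
}

asCrossMatrix <- function(Z, center) {
  if (is(Z, "CrossProducts")) Z <- Z@Z
  Z <- as.matrix(Z)
  if (center) Z <- centerColumns(Z)
  Z
}

## Build the requested kernels for a centered cross-product matrix at once,
## sharing the Gram matrix between the linear and Gaussian kernels.
buildKernels <- function(Z, kernels, nu = 1e-4, center = TRUE) {
  Z <- asCrossMatrix(Z, center)
  out <- vector("list", length(kernels))
  names(out) <- kernels
  G <- NULL
  for (k in kernels) {
    if (k == "linear") {
      G <- G %||% tcrossprod(Z)
      out[[k]] <- G
    } else if (k == "projection") {
      out[[k]] <- projectionKernel(Z, center = FALSE)
    } else if (k == "gaussian") {
      G <- G %||% tcrossprod(Z)
      d2 <- outer(diag(G), diag(G), "+") - 2 * G
      d2[d2 < 0] <- 0
      K <- exp(-nu * d2)
      diag(K) <- 1
      out[[k]] <- K
    } else stop("unknown kernel: ", k)
  }
  out
}
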