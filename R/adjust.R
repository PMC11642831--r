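## Mean/variance adjustment of pathway expression and construction of the
## individual-specific gene-correlation cross products.

## Mean-model design: [intercept | X | C | M]; rank-checked.
designMatrix <- function(data) {
  D <- cbind(`(Intercept)` = 1, data@X, data@covar, data@batch)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("mean-model design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  D
}

## Variance-model design: risk factor only by default (the variance effects
## of other variables can be included on request).
varianceDesign <- function(data, includeCovariates = FALSE) {
  if (includeCovariates)
    cbind(`(Intercept)` = 1, data@X, data@covar, data@batch)
  else
    cbind(`(Intercept)` = 1, data@X)
}

## least squares of every gene on a shared design, via one QR
lstsqFit <- function(Y, D, qrD = qr(D)) {
  coefs <- qr.coef(qrD, Y)
  fitted <- D %*% coefs
  list(coefs = coefs, fitted = fitted, e = Y - fitted, qr = qrD)
}

## Gamma IRLS with log link on squared residuals. For the log link the IRLS
## weights are identically 1, so each step is OLS on the working response;
## convergence is judged on the coefficients (squared residuals may be 0).
gammaLogFit <- function(y, D, qrD = qr(D), tol = 1e-8, maxit = 25L) {
  eta <- rep(log(mean(y) + 1e-300), length(y))
  beta <- NULL
  for (i in seq_len(maxit)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    betaNew <- qr.coef(qrD, z)
    eta <- drop(D %*% betaNew)
    eta <- pmin(pmax(eta, -700), 700)
    if (!is.null(beta) && max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  list(coefs = beta, fitted = exp(eta))
}

## Internal adjustment engine on plain matrices (reused per permutation when
## refitting). Returns raw residuals, conditional variances, standardized
## residuals, and the fitted mean surface.
adjustMatrix <- function(Y, D, Dv, groups, mode, qrD = qr(D), qrDv = qr(Dv),
                         tol = 1e-6, maxit = 20L, warnNonconverged = TRUE) {
  n <- nrow(Y); r <- ncol(Y)
  fit <- lstsqFit(Y, D, qrD)
  e <- fit$e
  coefs <- fit$coefs
  converged <- rep(TRUE, r)
  varCoefs <- NULL

  if (mode == "none") {
    s2 <- matrix(1, n, r)
  } else if (mode == "per-group") {
    pShared <- ncol(D) - nlevels(groups)   # parameters not tied to a group
    s2 <- matrix(NA_real_, n, r)
    gvar <- matrix(NA_real_, nlevels(groups), r,
                   dimnames = list(levels(groups), NULL))
    for (g in levels(groups)) {
      idx <- which(groups == g)
      ng <- length(idx)
      pg <- 1 + pShared * ng / n
      v <- colSums(e[idx, , drop = FALSE]^2) / (ng - pg)
      gvar[g, ] <- v
      s2[idx, ] <- rep(v, each = ng)
    }
    varCoefs <- gvar
  } else {  # dglm: iterate variance fit and reweighted mean fit jointly
    pv <- ncol(Dv)
    theta <- matrix(0, pv, r)
    for (it in seq_len(maxit)) {
      thetaNew <- matrix(NA_real_, pv, r)
      s2 <- matrix(NA_real_, n, r)
      for (k in seq_len(r)) {
        vf <- gammaLogFit(e[, k]^2, Dv, qrDv)
        thetaNew[, k] <- vf$coefs
        s2[, k] <- vf$fitted
      }
      ## reweighted mean fit, per gene (weights 1/s2 differ across genes)
      coefsNew <- matrix(NA_real_, ncol(D), r)
      for (k in seq_len(r)) {
        w <- 1 / s2[, k]
        sw <- sqrt(w)
        fitk <- qr.coef(qr(D * sw), Y[, k] * sw)
        coefsNew[, k] <- fitk
      }
      delta <- max(abs(thetaNew - theta), abs(coefsNew - coefs))
      theta <- thetaNew
      coefs <- coefsNew
      e <- Y - D %*% coefs
      if (delta < tol) break
    }
    if (delta >= tol) {
      converged[] <- FALSE
      if (warnNonconverged)
        warning("double-GLM did not converge in ", maxit,
                " iterations; last iterate used")
    }
    rownames(theta) <- colnames(Dv)
    varCoefs <- theta
  }

  if (any(s2 < 1e-12)) {
    bad <- unique(which(s2 < 1e-12, arr.ind = TRUE)[, 2L])
    stop("degenerate gene(s) with fitted variance below 1e-12: ",
         paste(bad, collapse = ", "))
  }
  rownames(coefs) <- colnames(D)
  list(e = e, s2 = s2, eStd = e / sqrt(s2), fitted = Y - e,
       coefs = coefs, varCoefs = varCoefs, converged = converged)
}

#' Fit the mean model of a pathway
#'
#' Per-gene least squares of expression on an intercept, the risk factor(s),
#' covariates and batch variables. Residuals carry the co-expression signal;
#' coefficients are retained so null pathways can be reconstructed.
#'
#' @param data a [PathwayData-class] object.
#' @return list with components \code{coefs} (p x r), \code{e} (n x r raw
#'   residuals), \code{fitted} (n x r), and \code{design}.
#' @examples
#' sim <- simulateNormalPathway(NormalSimConfig(n = 60, r = 3, seed = 2))
#' fit <- fitMeanModel(sim$data)
#' colMeans(fit$e)   # ~ 0 by construction
#' @export
fitMeanModel <- function(data) {
  stopifnot(is(data, "PathwayData"))
  D <- designMatrix(data)
  fit <- lstsqFit(data@Y, D)
  rownames(fit$coefs) <- colnames(D)
  colnames(fit$coefs) <- data@geneIds
  list(coefs = fit$coefs, e = fit$e, fitted = fit$fitted, design = D)
}

#' Estimate conditional variances of pathway residuals
#'
#' Variance effects of the risk factor would otherwise masquerade as
#' differential co-expression; this estimates \eqn{\sigma^2_{jk}} either
#' within each level of a categorical risk factor (\code{mode = "per-group"},
#' df-corrected) or by a double GLM (\code{mode = "dglm"}): a gamma GLM with
#' log link on the squared residuals, iterated with a reweighted mean fit
#' until the coefficients change by less than 1e-6 (at most 20 iterations).
#'
#' @param e n x r matrix of raw residuals (from [fitMeanModel()]).
#' @param data the [PathwayData-class] the residuals came from.
#' @param mode \code{"per-group"} (single categorical risk factor),
#'   \code{"dglm"} (any numeric design), or \code{"none"} (variances fixed
#'   at 1; for diagnostic use only).
#' @param includeCovariates include covariate and batch columns in the
#'   variance model (dglm only). Default uses the risk factor(s) only.
#' @return n x r matrix of variance estimates with attributes
#'   \code{varCoefs}, \code{converged}, and (dglm) \code{residuals} and
#'   \code{meanCoefs} holding the jointly re-estimated mean fit.
#' @export
estimateVariance <- function(e, data, mode = c("dglm", "per-group", "none"),
                             includeCovariates = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(data, "PathwayData"))
  if (mode == "per-group") {
    if (is.null(data@groups))
      stop("per-group variance estimation requires a single categorical ",
           "risk factor")
    if (any(table(data@groups) < 3L))
      stop("each risk-factor level needs >= 3 samples")
  }
  D <- designMatrix(data)
  Dv <- varianceDesign(data, includeCovariates)
  if (mode == "dglm") {
    adj <- adjustMatrix(data@Y, D, Dv, data@groups, "dglm")
  } else {
    ## per-group / none operate on the supplied residuals directly
    adj <- adjustMatrix(data@Y, D, Dv, data@groups, mode)
    adj$e <- e
    if (mode == "per-group") {
      ## recompute from the supplied residuals for faithfulness to the input
      pShared <- ncol(D) - nlevels(data@groups)
      n <- nrow(e)
      s2 <- matrix(NA_real_, n, ncol(e))
      for (g in levels(data@groups)) {
        idx <- which(data@groups == g)
        ng <- length(idx)
        pg <- 1 + pShared * ng / n
        v <- colSums(e[idx, , drop = FALSE]^2) / (ng - pg)
        s2[idx, ] <- rep(v, each = ng)
      }
      if (any(s2 < 1e-12))
        stop("degenerate gene(s) with fitted variance below 1e-12")
      adj$s2 <- s2
    }
  }
  s2 <- adj$s2
  attr(s2, "varCoefs") <- adj$varCoefs
  attr(s2, "converged") <- adj$converged
  if (mode == "dglm") {
    attr(s2, "residuals") <- adj$e
    attr(s2, "meanCoefs") <- adj$coefs
  }
  s2
}

#' Standardize residuals by their conditional standard deviation
#'
#' @param e n x r raw residual matrix.
#' @param s2 n x r strictly positive conditional variance estimates.
#' @return n x r matrix of standardized residuals e / sqrt(s2).
#' @export
standardizeResiduals <- function(e, s2) {
  if (any(s2 <= 0)) stop("conditional variances must be strictly positive")
  if (!identical(dim(e), dim(s2))) stop("e and s2 must share dimensions")
  e / sqrt(s2)
}

## lexicographic gene-pair index (1,2), (1,3), ..., (r-1, r)
genePairs <- function(r) {
  idx <- t(utils::combn(r, 2L))
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("k1", "k2")
  idx
}

#' Cross products of standardized residuals
#'
#' Forms the n x q matrix Z of individual-specific gene-correlation
#' estimates, one column per gene pair (lexicographic order), q = r(r-1)/2.
#' Column means of Z estimate the pairwise residual correlations.
#'
#' @param eStd n x r matrix of standardized residuals, or an
#'   [AdjustedResiduals-class] object.
#' @return A [CrossProducts-class] object.
#' @export
crossProducts <- function(eStd) {
  if (is(eStd, "AdjustedResiduals")) eStd <- eStd@eStd
  r <- ncol(eStd)
  if (r < 2L) stop("need at least 2 genes to form cross products")
  pairs <- genePairs(r)
  Z <- eStd[, pairs[, 1L], drop = FALSE] * eStd[, pairs[, 2L], drop = FALSE]
  colnames(Z) <- paste0(pairs[, 1L], ":", pairs[, 2L])
  new("CrossProducts", Z = Z, pairIndex = pairs)
}

#' Full mean/variance adjustment of a pathway
#'
#' Convenience wrapper running [fitMeanModel()], [estimateVariance()] and
#' [standardizeResiduals()] with a single variance-mode switch. With
#' \code{varianceMode = "auto"}, a single categorical risk factor uses
#' per-group variances (plain OLS mean fit) and any other design uses the
#' joint double GLM.
#'
#' @param data a [PathwayData-class] object.
#' @param varianceMode one of \code{"auto"}, \code{"dglm"},
#'   \code{"per-group"}, \code{"none"}.
#' @param includeCovariatesInVariance include covariates/batch in the dglm
#'   variance model.
#' @return An [AdjustedResiduals-class] object.
#' @examples
#' sim <- simulateNormalPathway(NormalSimConfig(n = 80, r = 5, seed = 3))
#' adj <- adjustPathway(sim$data)
#' adj
#' @export
adjustPathway <- function(data,
                          varianceMode = c("auto", "dglm", "per-group", "none"),
                          includeCovariatesInVariance = FALSE) {
  varianceMode <- match.arg(varianceMode)
  if (varianceMode == "auto")
    varianceMode <- if (!is.null(data@groups)) "per-group" else "dglm"
  D <- designMatrix(data)
  Dv <- varianceDesign(data, includeCovariatesInVariance)
  adj <- adjustMatrix(data@Y, D, Dv, data@groups, varianceMode)
  new("AdjustedResiduals",
      e = adj$e, s2 = adj$s2, eStd = adj$eStd, fitted = adj$fitted,
      meanCoefs = adj$coefs, design = D, varianceMode = varianceMode,
      varCoefs = adj$varCoefs, converged = adj$converged)
}
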