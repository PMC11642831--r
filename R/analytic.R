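## Large-sample analytic null: the HSIC statistic is asymptotically a
## weighted sum of 1-df chi-squares with weights given by products of the
## nonzero eigenvalues of the double-centered kernels, divided by n. The
## tail probability is evaluated by Imhof's exact one-dimensional integral.

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes \eqn{P(\sum_i w_i \chi^2_{1,i} > q)} for nonnegative weights by
#' numerical evaluation of Imhof's integral.
#'
#' @param q quantile (scalar).
#' @param weights nonnegative weights.
#' @return upper tail probability in \[0, 1\].
#' @examples
#' weightedChisqTail(1, 1)            # pchisq(1, 1, lower.tail = FALSE)
#' weightedChisqTail(2, c(1, 1))      # pchisq(2, 2, lower.tail = FALSE)
#' @export
weightedChisqTail <- function(q, weights) {
  weights <- weights[weights != 0]
  if (!length(weights)) return(as.numeric(q <= 0))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (length(weights) == 1L)
    return(stats::pchisq(q / weights, df = 1, lower.tail = FALSE))
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(weights, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(weights^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- (sum(weights) - q) / 2
    out
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                          subdivisions = 2000L, stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 0), 1)
}

#' Analytic (large-sample) p-value for the HSIC statistic
#'
#' Approximates the permutation null by the weighted chi-square limit: the
#' weights are products of the nonzero eigenvalues of the double-centered
#' kernel matrices, normalized so their sum matches the exact null mean
#' \eqn{\mathrm{tr}(K_Z^c)\,\mathrm{tr}(K_X^c)/n^2} of the statistic
#' (equivalently, products of the eigenvalues of the empirical kernel
#' operators \eqn{K/n}, rescaled by \eqn{n}). Intended for large
#' samples; a warning is issued for n < 1000 where the approximation is
#' unreliable and the permutation test should be used instead.
#'
#' @param KZ,KX n x n kernel matrices (double-centered internally).
#' @param Tobs observed HSIC statistic from [hsicStatistic()].
#' @param Z,X optional factor shortcuts: when the kernels are linear
#'   (\code{KZ = Z Z'}, \code{KX = X X'} on centered columns), passing the
#'   n x q and n x L factors computes the eigenvalues from the small
#'   crossproduct matrices instead of the n x n kernels.
#' @param tol relative eigenvalue-product cutoff (default 1e-12).
#' @return analytic p-value.
#' @export
analyticPvalue <- function(KZ, KX, Tobs, Z = NULL, X = NULL, tol = 1e-12) {
  if (is.null(Z)) {
    n <- nrow(KZ)
    lamZ <- kernelEigenvalues(KZ)
  } else {
    Zc <- centerColumns(as.matrix(Z))
    n <- nrow(Zc)
    lamZ <- eigen(crossprod(Zc), symmetric = TRUE, only.values = TRUE)$values
  }
  if (is.null(X)) {
    lamX <- kernelEigenvalues(KX)
  } else {
    Xs <- riskScores(as.matrix(X))
    lamX <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  }
  if (n < 1000)
    warning("analytic null is a large-sample approximation; n = ", n,
            " is small, prefer the permutation test")
  negTol <- -1e-8 * max(abs(c(lamZ, lamX)), 1)
  if (any(lamZ < negTol) || any(lamX < negTol))
    stop("kernels are not positive semidefinite within tolerance")
  lamZ <- lamZ[lamZ > 0]
  lamX <- lamX[lamX > 0]
  w <- as.numeric(outer(lamZ, lamX)) / n^2
  w <- w[w > tol * max(w)]
  weightedChisqTail(Tobs, w)
}

## eigenvalues of the double-centered kernel H K H
kernelEigenvalues <- function(K) {
  n <- nrow(K)
  rm <- rowMeans(K)
  Kc <- K - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + mean(K)
  eigen(Kc, symmetric = TRUE, only.values = TRUE)$values
}
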