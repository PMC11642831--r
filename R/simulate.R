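## Simulation engines: the multivariate-normal pathway model with
## correlation-specific risk-factor effects, and the negative-binomial
## genome with latent variance interactions. Defaults reproduce the study
## conditions of the simulation design (n = 300, r = 10, continuous risk
## factor on (0, 2), baseline correlations on (0.25, 0.5), etc.).

#' Configuration for the multivariate-normal pathway simulator
#'
#' @param n samples (default 300).
#' @param r pathway size (default 10; 50 reflects larger pathways).
#' @param riskType \code{"continuous"} (X ~ Uniform(0, 2)) or
#'   \code{"categorical"} (X ~ Bernoulli(0.5)).
#' @param sparsity proportion of genes with no differential co-expression.
#' @param architecture \code{"Positive"} (all effect directions +1) or
#'   \code{"PositiveNegative"} (random per-gene signs).
#' @param tauRange range for the correlation-specific effect size tau
#'   (default c(0.1, 0.2)); \code{NULL} for the null tau = 0.
#' @param rhoRange range of the baseline gene-pair correlation, drawn per
#'   individual (default c(0.25, 0.5)); set \code{fixedRho} for a constant.
#' @param deltaRange range of the per-gene variance effect size delta.
#' @param nFactors number of risk factors L (1, or 3 for the multi-factor
#'   design, where the effective factor is (2/3) of their sum).
#' @param fixedRho optional scalar overriding \code{rhoRange}.
#' @param seed optional RNG seed.
#' @return validated configuration list.
#' @export
NormalSimConfig <- function(n = 300L, r = 10L,
                            riskType = c("continuous", "categorical"),
                            sparsity = 0, architecture = c("Positive",
                                                           "PositiveNegative"),
                            tauRange = c(0.1, 0.2),
                            rhoRange = c(0.25, 0.50),
                            deltaRange = c(0.0, 0.1),
                            nFactors = 1L, fixedRho = NULL, seed = NULL) {
  riskType <- match.arg(riskType)
  architecture <- match.arg(architecture)
  stopifnot(n >= 10, r >= 2, sparsity >= 0, sparsity <= 1,
            nFactors %in% c(1L, 3L))
  maxX <- if (riskType == "continuous") 2 else 1
  maxTau <- if (is.null(tauRange)) 0 else max(tauRange)
  maxRho <- if (is.null(fixedRho)) max(rhoRange) else fixedRho
  if (maxRho + maxTau * maxX > 1)
    stop("invalid correlation: max(rho) + tau * max(X) exceeds 1")
  structure(list(n = as.integer(n), r = as.integer(r), riskType = riskType,
                 sparsity = sparsity, architecture = architecture,
                 tauRange = tauRange, rhoRange = rhoRange,
                 deltaRange = deltaRange, nFactors = as.integer(nFactors),
                 fixedRho = fixedRho, seed = seed),
            class = "NormalSimConfig")
}

#' Simulate one pathway from the multivariate-normal model
#'
#' Generates expression with risk-factor effects on the mean
#' (\eqn{E[Y_{jk}|X,C] = \alpha_k + X_j + C_j}), the log variance
#' (\eqn{\log Var = 1 + \delta_k X_j}), and the gene-pair correlation
#' (\eqn{\rho_j + \tau X_j} among differential genes, with per-gene signs
#' under the Positive/Negative architecture). A two-factor latent
#' construction realizes these moments exactly:
#' \deqn{Y_{jk} = \alpha_k + X_j + C_j + \sigma_{jk}(\sqrt{\rho_j} A_j +
#'   1_{k \in D} s_k \sqrt{\tau X_j} B_j +
#'   \sqrt{1 - \rho_j - 1_{k \in D}\tau X_j}\,\epsilon_{jk})}
#' with \eqn{A_j, B_j, \epsilon_{jk}} iid standard normal and
#' \eqn{\sigma^2_{jk} = \exp(1 + \delta_k X_j)}. For three risk factors the
#' effective factor \eqn{(2/3)\sum_l X_{jl}} replaces \eqn{X_j} in all three
#' moment equations.
#'
#' @param cfg a [NormalSimConfig()] configuration.
#' @return list with \code{data} (a [PathwayData-class]) and \code{truth}
#'   (differential gene set D, signs, tau, delta, rho).
#' @export
simulateNormalPathway <- function(cfg) {
  stopifnot(inherits(cfg, "NormalSimConfig"))
  withSeed(cfg$seed, {
    n <- cfg$n; r <- cfg$r; L <- cfg$nFactors
    X <- if (cfg$riskType == "continuous")
      matrix(runif(n * L, 0, 2), n, L)
    else
      matrix(rbinom(n * L, 1L, 0.5), n, L)
    Xeff <- if (L == 1L) X[, 1L] else (2 / 3) * rowSums(X)
    C <- runif(n, 0, 2)
    alpha <- rnorm(r)
    delta <- runif(r, cfg$deltaRange[1L], cfg$deltaRange[2L])
    rho <- if (is.null(cfg$fixedRho))
      runif(n, cfg$rhoRange[1L], cfg$rhoRange[2L]) else rep(cfg$fixedRho, n)
    tau <- if (is.null(cfg$tauRange)) 0 else
      runif(1L, cfg$tauRange[1L], cfg$tauRange[2L])
    nDiff <- ceiling((1 - cfg$sparsity) * r)
    D <- if (nDiff > 0) sort(sample.int(r, nDiff)) else integer(0)
    s <- rep(1, r)
    if (cfg$architecture == "PositiveNegative")
      s[D] <- sample(c(-1, 1), length(D), replace = TRUE)
    if (max(rho) + tau * max(Xeff) > 1)
      stop("invalid correlation: rho + tau * X exceeds 1")
    A <- rnorm(n); B <- rnorm(n)
    eps <- matrix(rnorm(n * r), n, r)
    inD <- as.numeric(seq_len(r) %in% D)
    sigma <- exp(outer(Xeff, delta) / 2 + 0.5)    # sqrt of exp(1 + delta X)
    shareTau <- outer(tau * Xeff, inD)            # n x r
    latent <- sqrt(rho) * A +
      t(s * inD * t(sqrt(shareTau) * B)) +
      sqrt(pmax(1 - rho - shareTau, 0)) * eps
    Y <- matrix(alpha, n, r, byrow = TRUE) + Xeff + C + sigma * latent
    colnames(Y) <- paste0("gene", seq_len(r))
    Xin <- if (cfg$riskType == "categorical" && L == 1L)
      factor(X[, 1L]) else X
    data <- PathwayData(Y, Xin, covariates = C)
    list(data = data,
         truth = list(differential = D, signs = s, tau = tau,
                      delta = delta, rho = rho, alpha = alpha))
  })
}

#' Configuration for the negative-binomial genome simulator
#'
#' @param nGenes number of genes (default 10000).
#' @param n samples (default 300).
#' @param dispersion NB dispersion phi in Var = mu + phi mu^2 (default 0.25,
#'   reflecting human data sets).
#' @param alphaMeanlog,alphaSdlog lognormal parameters of the baseline count
#'   size alpha_k (default meanlog 5.54, sdlog 0.697).
#' @param betaSd,gammaSd SDs of the risk-factor and covariate log-scale
#'   effects (default 0.1, i.e. variance 0.01).
#' @param deltaSd SD of the latent variance-interaction effect (default
#'   0.025, i.e. variance 6.25e-4).
#' @param librarySizes candidate per-sample expected totals, drawn
#'   equiprobably (default 2e6 and 1e7).
#' @param pathwaySize genes per pathway when partitioning (default 10).
#' @param riskType risk factor distribution as in [NormalSimConfig()].
#' @param seed optional RNG seed.
#' @return validated configuration list.
#' @export
NbSimConfig <- function(nGenes = 10000L, n = 300L, dispersion = 0.25,
                        alphaMeanlog = 5.54, alphaSdlog = 0.697,
                        betaSd = 0.1, gammaSd = 0.1, deltaSd = 0.025,
                        librarySizes = c(2e6, 1e7), pathwaySize = 10L,
                        riskType = c("continuous", "categorical"),
                        seed = NULL) {
  riskType <- match.arg(riskType)
  stopifnot(dispersion > 0, all(librarySizes > 0), nGenes >= pathwaySize)
  structure(list(nGenes = as.integer(nGenes), n = as.integer(n),
                 dispersion = dispersion, alphaMeanlog = alphaMeanlog,
                 alphaSdlog = alphaSdlog, betaSd = betaSd, gammaSd = gammaSd,
                 deltaSd = deltaSd, librarySizes = librarySizes,
                 pathwaySize = as.integer(pathwaySize), riskType = riskType,
                 seed = seed),
            class = "NbSimConfig")
}

#' Simulate an RNA-seq count data set from the negative-binomial model
#'
#' Per-gene per-sample expected counts follow
#' \eqn{\mu_{jk} = \alpha_k \exp(\beta_k X_j + \gamma_k C_j +
#' \delta_k X_j U_{jk})} with latent \eqn{U_{jk} \sim N(0,1)}; the
#' interaction \eqn{X_j U_{jk}} is a pure variance-type effect, so every
#' pathway is null for differential co-expression. Expected means are
#' scaled per sample so totals match the drawn library size (scaling the
#' means, not thinning counts, preserves the NB dispersion), then counts
#' are drawn with \eqn{Var = \mu + \phi\mu^2}. Genes are partitioned into
#' disjoint consecutive pathways of the configured size.
#'
#' @param cfg an [NbSimConfig()] configuration.
#' @return list with \code{counts} (n x nGenes integer matrix),
#'   \code{librarySizes}, \code{X}, \code{C}, and \code{pathways} (a named
#'   list of gene-index vectors).
#' @export
simulateNbDataset <- function(cfg) {
  stopifnot(inherits(cfg, "NbSimConfig"))
  withSeed(cfg$seed, {
    n <- cfg$n; G <- cfg$nGenes
    X <- if (cfg$riskType == "continuous") runif(n, 0, 2) else
      rbinom(n, 1L, 0.5)
    C <- runif(n, 0, 2)
    alpha <- rlnorm(G, cfg$alphaMeanlog, cfg$alphaSdlog)
    beta <- rnorm(G, 0, cfg$betaSd)
    gamma <- rnorm(G, 0, cfg$gammaSd)
    delta <- rnorm(G, 0, cfg$deltaSd)
    U <- matrix(rnorm(n * G), n, G)
    eta <- outer(X, beta) + outer(C, gamma) +
      U * outer(X, delta)
    mu <- sweep(exp(eta), 2L, alpha, "*")
    lib <- cfg$librarySizes[sample.int(length(cfg$librarySizes), n,
                                       replace = TRUE)]
    mu <- mu * (lib / rowSums(mu))
    counts <- matrix(rnbinom(n * G, mu = mu, size = 1 / cfg$dispersion),
                     n, G)
    colnames(counts) <- paste0("gene", seq_len(G))
    rownames(counts) <- paste0("sample", seq_len(n))
    nPath <- G %/% cfg$pathwaySize
    pathways <- split(seq_len(nPath * cfg$pathwaySize),
                      rep(seq_len(nPath), each = cfg$pathwaySize))
    names(pathways) <- paste0("PWY", seq_len(nPath))
    list(counts = counts, librarySizes = lib, X = X, C = C,
         pathways = pathways,
         params = list(alpha = alpha, beta = beta, gamma = gamma,
                       delta = delta))
  })
}

#' Log-transform counts and extract the library-size covariate
#'
#' \code{log2(count + pseudocount)} expression plus the log of each
#' sample's total counts, for use as a fixed covariate in the mean model.
#'
#' @param counts nonnegative integer matrix, samples x genes.
#' @param pseudocount added before the log (default 1).
#' @return list with \code{expression} (same shape as counts) and
#'   \code{logLibSize} (length-n vector of log total counts).
#' @export
logTransformCounts <- function(counts, pseudocount = 1) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  list(expression = log2(counts + pseudocount),
       logLibSize = log(rowSums(counts)))
}

#' Write a simulated study to disk
#'
#' Emits the expression matrix, sample metadata, pathway GMT, and truth
#' labels as tab-separated text, round-trippable through [runStudy()].
#'
#' @param expression samples x genes numeric matrix.
#' @param metadata data.frame keyed on \code{sample_id}.
#' @param pathways named list of gene-identifier vectors.
#' @param truth optional data.frame of truth labels.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulatedStudy <- function(expression, metadata, pathways, truth = NULL,
                                dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exprPath <- file.path(dir, "expression.tsv")
  metaPath <- file.path(dir, "metadata.tsv")
  gmtPath <- file.path(dir, "pathways.gmt")
  df <- data.frame(sample_id = rownames(expression) %||%
                     paste0("sample", seq_len(nrow(expression))),
                   expression, check.names = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metadata, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "simulated", pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, gmtPath)
  paths <- c(expression = exprPath, metadata = metaPath, genesets = gmtPath)
  if (!is.null(truth)) {
    truthPath <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = truthPath)
  }
  invisible(paths)
}
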