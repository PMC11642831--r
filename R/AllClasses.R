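#' @import methods
NULL

setClassUnion("factorOrNULL", c("factor", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Pathway expression data with risk factors, covariates and batch variables
#'
#' Container for the expression submatrix of one gene set together with the
#' sample-level design used for adjustment: one or more risk factors of
#' interest, optional covariates, and optional batch variables. Expression is
#' expected on an approximately normal scale (e.g. logCPM or log2 counts).
#'
#' @slot Y numeric matrix, n samples x r genes.
#' @slot X numeric matrix, n x L risk factor(s); categorical factors are stored
#'   as treatment-coded indicator columns.
#' @slot groups factor of length n when the (single) risk factor is
#'   categorical, otherwise \code{NULL}; drives per-group variance estimation.
#' @slot covar numeric matrix, n x lC covariates (may have zero columns).
#' @slot batch numeric matrix, n x lM batch variables (may have zero columns).
#' @slot geneIds,sampleIds character labels.
#'
#' @seealso [PathwayData()] for the user constructor.
#' @export
setClass("PathwayData",
  representation(
    Y = "matrix", X = "matrix", groups = "factorOrNULL",
    covar = "matrix", batch = "matrix",
    geneIds = "character", sampleIds = "character"
  )
)

setValidity("PathwayData", function(object) {
  msg <- character()
  n <- nrow(object@Y)
  if (anyNA(object@Y)) msg <- c(msg, "Y contains missing values")
  if (anyNA(object@X)) msg <- c(msg, "X contains missing values")
  if (n < 10L) msg <- c(msg, "need at least 10 samples")
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) != nrow(Y)")
  if (nrow(object@covar) != n) msg <- c(msg, "nrow(C) != nrow(Y)")
  if (nrow(object@batch) != n) msg <- c(msg, "nrow(M) != nrow(Y)")
  if (length(object@geneIds) != ncol(object@Y))
    msg <- c(msg, "geneIds length != ncol(Y)")
  if (length(object@sampleIds) != n)
    msg <- c(msg, "sampleIds length != nrow(Y)")
  v <- apply(object@Y, 2L, stats::var)
  if (any(v <= 0))
    msg <- c(msg, paste0("constant gene column(s): ",
                         paste(object@geneIds[v <= 0], collapse = ", ")))
  if (!is.null(object@groups)) {
    tab <- table(object@groups)
    if (length(tab) < 2L)
      msg <- c(msg, "categorical risk factor needs >= 2 levels")
    if (any(tab < 3L))
      msg <- c(msg, "each risk-factor level needs >= 3 samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayData object
#'
#' @param Y numeric matrix of expression values, samples in rows and genes in
#'   columns (approximately normal scale, e.g. logCPM).
#' @param X risk factor(s): a numeric vector/matrix (n x L), or a factor for a
#'   single categorical risk factor. Factors are expanded to treatment-coded
#'   indicator columns (sorted level order); the level labels are retained for
#'   per-group variance estimation.
#' @param covariates optional numeric matrix/vector of covariates (n x lC).
#' @param batch optional numeric matrix/vector of batch variables (n x lM).
#' @param geneIds,sampleIds optional labels; default to dimnames of \code{Y}.
#'
#' @return A [PathwayData-class] object.
#' @examples
#' sim <- simulateNormalPathway(NormalSimConfig(n = 50, r = 4, seed = 1))
#' pd <- sim$data
#' pd
#' @export
PathwayData <- function(Y, X, covariates = NULL, batch = NULL,
                        geneIds = NULL, sampleIds = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  groups <- NULL
  if (is.factor(X) || is.character(X)) {
    groups <- factor(as.character(X), levels = sort(unique(as.character(X))))
    lev <- levels(groups)
    Xm <- vapply(lev[-1L], function(l) as.numeric(groups == l), numeric(n))
    Xm <- matrix(Xm, nrow = n,
                 dimnames = list(NULL, paste0("X", lev[-1L])))
  } else {
    Xm <- as.matrix(X)
    storage.mode(Xm) <- "double"
    if (is.null(colnames(Xm)))
      colnames(Xm) <- paste0("X", seq_len(ncol(Xm)))
  }
  asmat <- function(v, prefix) {
    if (is.null(v)) return(matrix(numeric(0), nrow = n, ncol = 0L))
    m <- as.matrix(v)
    storage.mode(m) <- "double"
    if (is.null(colnames(m)) && ncol(m))
      colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    m
  }
  if (is.null(geneIds))
    geneIds <- colnames(Y) %||% paste0("gene", seq_len(ncol(Y)))
  if (is.null(sampleIds))
    sampleIds <- rownames(Y) %||% paste0("sample", seq_len(n))
  new("PathwayData", Y = Y, X = Xm, groups = groups,
      covar = asmat(covariates, "C"), batch = asmat(batch, "M"),
      geneIds = as.character(geneIds), sampleIds = as.character(sampleIds))
}

#' Build a PathwayData object from a SummarizedExperiment
#'
#' Extracts one assay (genes x samples, transposed internally to samples x
#' genes) and named columns of \code{colData} as risk factor(s), covariates
#' and batch variables.
#'
#' @param se a \code{SummarizedExperiment}.
#' @param riskFactor character vector of colData column name(s).
#' @param covariates,batch optional character vectors of colData column names.
#' @param assay assay name or index (default first).
#' @return A [PathwayData-class] object.
#' @export
pathwayDataFromSE <- function(se, riskFactor, covariates = NULL,
                              batch = NULL, assay = 1L) {
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("the SummarizedExperiment package is required for this constructor")
  Y <- t(SummarizedExperiment::assay(se, assay))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  missing <- setdiff(c(riskFactor, covariates, batch), colnames(cd))
  if (length(missing))
    stop("colData column(s) not found: ", paste(missing, collapse = ", "))
  X <- if (length(riskFactor) == 1L) cd[[riskFactor]] else
    as.matrix(cd[, riskFactor, drop = FALSE])
  grab <- function(cols) if (is.null(cols)) NULL else
    as.matrix(cd[, cols, drop = FALSE])
  PathwayData(Y, X, covariates = grab(covariates), batch = grab(batch))
}

#' Adjusted (standardized) residuals of a pathway
#'
#' Holds the raw residuals after removing mean effects of the risk factor(s),
#' covariates and batch variables, the estimated conditional variances, and
#' the standardized residuals used to form individual-specific gene
#' correlations. Retains the fitted means and design so null pathways can be
#' reconstructed exactly.
#'
#' @slot e,s2,eStd numeric matrices, n x r: raw residuals, conditional
#'   variance estimates, standardized residuals e/sqrt(s2).
#' @slot fitted numeric matrix n x r of fitted mean values.
#' @slot meanCoefs numeric matrix p x r of mean-model coefficients.
#' @slot design numeric matrix n x p mean-model design.
#' @slot varianceMode one of "per-group", "dglm", "none".
#' @slot varCoefs variance-model coefficients (dglm) or per-group variances.
#' @slot converged logical per gene (dglm); all TRUE otherwise.
#' @export
setClass("AdjustedResiduals",
  representation(
    e = "matrix", s2 = "matrix", eStd = "matrix", fitted = "matrix",
    meanCoefs = "matrix", design = "matrix", varianceMode = "character",
    varCoefs = "ANY", converged = "logical"
  )
)

setValidity("AdjustedResiduals", function(object) {
  msg <- character()
  if (any(object@s2 <= 0)) msg <- c(msg, "conditional variances must be > 0")
  dm <- dim(object@e)
  if (!identical(dim(object@s2), dm) || !identical(dim(object@eStd), dm))
    msg <- c(msg, "e, s2 and eStd must share dimensions")
  if (length(msg)) msg else TRUE
})

#' Cross products of standardized residuals
#'
#' The n x q matrix Z of individual-specific gene correlation estimates, one
#' column per gene pair in lexicographic order (1,2), (1,3), ..., (r-1, r).
#'
#' @slot Z numeric matrix n x q, q = r(r-1)/2.
#' @slot pairIndex integer matrix q x 2 of gene-pair column indices.
#' @export
setClass("CrossProducts",
  representation(Z = "matrix", pairIndex = "matrix")
)

setValidity("CrossProducts", function(object) {
  if (nrow(object@pairIndex) != ncol(object@Z))
    "pairIndex rows must match ncol(Z)" else TRUE
})

#' Result of a kernel differential co-expression test
#'
#' @slot statObs named numeric of observed HSIC statistics per kernel.
#' @slot statNull numeric matrix B x n_kernels of permutation null statistics.
#' @slot pKernel named numeric of per-kernel empirical p-values.
#' @slot statFisher observed Fisher combination statistic -2 sum log p_d.
#' @slot pCombined combined empirical p-value.
#' @slot pEigengene eigengene comparator p-value (NA when not computed).
#' @slot B number of permutations; @slot seed RNG seed (NA if unset).
#' @slot kernels kernel names used; @slot refit whether the permutation null
#'   re-ran the full mean/variance adjustment; @slot varianceMode variance
#'   estimation mode used.
#' @export
setClass("KdcaResult",
  representation(
    statObs = "numeric", statNull = "matrix", pKernel = "numeric",
    statFisher = "numeric", pCombined = "numeric", pEigengene = "numeric",
    B = "integer", seed = "integer", kernels = "character",
    refit = "logical", varianceMode = "character"
  )
)

setValidity("KdcaResult", function(object) {
  msg <- character()
  B <- object@B
  pv <- c(object@pKernel, object@pCombined)
  if (any(pv < 1 / (B + 1) - 1e-12 | pv > 1 + 1e-12))
    msg <- c(msg, "empirical p-values must lie in [1/(B+1), 1]")
  if (length(msg)) msg else TRUE
})

#' A named collection of gene sets
#'
#' @slot sets named list; each element a character vector of gene identifiers.
#' @slot provenance free-text origin of the collection.
#' @export
setClass("GeneSetList",
  representation(sets = "list", provenance = "character")
)

## ---- accessors ----

#' Accessors for KernelDCA classes
#'
#' @param object a KernelDCA object.
#' @name accessors
#' @aliases expressionMatrix riskFactors standardizedResiduals
#'   conditionalVariances meanCoefficients crossProductMatrix pairIndex
#'   kernelStats kernelPvalues combinedPvalue eigengenePvalue nullStats
#'   geneSets
NULL

#' @rdname accessors
#' @export
setGeneric("expressionMatrix", function(object) standardGeneric("expressionMatrix"))
#' @rdname accessors
#' @export
setMethod("expressionMatrix", "PathwayData", function(object) object@Y)

#' @rdname accessors
#' @export
setGeneric("riskFactors", function(object) standardGeneric("riskFactors"))
#' @rdname accessors
#' @export
setMethod("riskFactors", "PathwayData", function(object) object@X)

#' @rdname accessors
#' @export
setGeneric("standardizedResiduals",
           function(object) standardGeneric("standardizedResiduals"))
#' @rdname accessors
#' @export
setMethod("standardizedResiduals", "AdjustedResiduals",
          function(object) object@eStd)

#' @rdname accessors
#' @export
setGeneric("conditionalVariances",
           function(object) standardGeneric("conditionalVariances"))
#' @rdname accessors
#' @export
setMethod("conditionalVariances", "AdjustedResiduals",
          function(object) object@s2)

#' @rdname accessors
#' @export
setGeneric("meanCoefficients",
           function(object) standardGeneric("meanCoefficients"))
#' @rdname accessors
#' @export
setMethod("meanCoefficients", "AdjustedResiduals",
          function(object) object@meanCoefs)

#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("residuals", "AdjustedResiduals", function(object, ...) object@e)

#' @rdname accessors
#' @export
setGeneric("crossProductMatrix",
           function(object) standardGeneric("crossProductMatrix"))
#' @rdname accessors
#' @export
setMethod("crossProductMatrix", "CrossProducts", function(object) object@Z)

#' @rdname accessors
#' @export
setGeneric("pairIndex", function(object) standardGeneric("pairIndex"))
#' @rdname accessors
#' @export
setMethod("pairIndex", "CrossProducts", function(object) object@pairIndex)

#' @rdname accessors
#' @export
setGeneric("kernelStats", function(object) standardGeneric("kernelStats"))
#' @rdname accessors
#' @export
setMethod("kernelStats", "KdcaResult", function(object) object@statObs)

#' @rdname accessors
#' @export
setGeneric("kernelPvalues", function(object) standardGeneric("kernelPvalues"))
#' @rdname accessors
#' @export
setMethod("kernelPvalues", "KdcaResult", function(object) object@pKernel)

#' @rdname accessors
#' @export
setGeneric("combinedPvalue", function(object) standardGeneric("combinedPvalue"))
#' @rdname accessors
#' @export
setMethod("combinedPvalue", "KdcaResult", function(object) object@pCombined)

#' @rdname accessors
#' @export
setGeneric("eigengenePvalue", function(object) standardGeneric("eigengenePvalue"))
#' @rdname accessors
#' @export
setMethod("eigengenePvalue", "KdcaResult", function(object) object@pEigengene)

#' @rdname accessors
#' @export
setGeneric("nullStats", function(object) standardGeneric("nullStats"))
#' @rdname accessors
#' @export
setMethod("nullStats", "KdcaResult", function(object) object@statNull)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(object) object@sets)

## ---- show ----

setMethod("show", "PathwayData", function(object) {
  cat("PathwayData:", nrow(object@Y), "samples x", ncol(object@Y), "genes\n")
  cat("  risk factors:", ncol(object@X),
      if (!is.null(object@groups))
        paste0("(categorical: ", nlevels(object@groups), " levels)") else
        "(numeric)", "\n")
  cat("  covariates:", ncol(object@covar), " batch:", ncol(object@batch), "\n")
})

setMethod("show", "AdjustedResiduals", function(object) {
  cat("AdjustedResiduals:", nrow(object@e), "samples x", ncol(object@e),
      "genes; variance mode:", object@varianceMode, "\n")
  if (!all(object@converged))
    cat("  warning:", sum(!object@converged), "gene(s) flagged non-converged\n")
})

setMethod("show", "CrossProducts", function(object) {
  cat("CrossProducts:", nrow(object@Z), "samples x", ncol(object@Z),
      "gene pairs\n")
})

setMethod("show", "KdcaResult", function(object) {
  cat("KdcaResult (B =", object@B, "permutations)\n")
  for (k in names(object@pKernel))
    cat(sprintf("  %-10s T = %10.4f   p = %.4g\n", k,
                object@statObs[k], object@pKernel[k]))
  if (length(object@pKernel) > 1L)
    cat(sprintf("  %-10s T' = %9.4f   p = %.4g\n", "combined",
                object@statFisher, object@pCombined))
  if (!is.na(object@pEigengene))
    cat(sprintf("  %-10s            p = %.4g\n", "eigengene",
                object@pEigengene))
})

setMethod("show", "GeneSetList", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetList:", length(object@sets), "sets")
  if (length(sz)) cat("; sizes", min(sz), "-", max(sz))
  cat("\n")
})
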