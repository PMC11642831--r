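## End-to-end orchestration: GMT gene sets, logCPM preprocessing, and the
## per-pathway study driver with BH FDR control.

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member gene identifiers.
#' Duplicate members within a set are removed with a warning; lines with
#' fewer than three fields are an error.
#'
#' @param path path to a GMT file.
#' @param provenance optional provenance string (defaults to the path).
#' @return A [GeneSetList-class] object.
#' @export
readGmt <- function(path, provenance = path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(new("GeneSetList", sets = setNames(list(), character(0)),
               provenance = as.character(provenance)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate gene identifiers in set '", fields[1L],
              "' deduplicated")
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  new("GeneSetList", sets = sets, provenance = as.character(provenance))
}

#' Filter and transform raw counts to logCPM
#'
#' logCPM = log2((count + 0.5) / (libsize + 1) * 1e6). Genes with logCPM
#' below \code{minLogCpm} in at least half the samples are removed, then the
#' \code{topK} most variable surviving genes are retained.
#'
#' @param counts raw count matrix; samples x genes by default.
#' @param genesInRows set TRUE if genes are in rows (transposed internally).
#' @param minLogCpm expression floor (default 1).
#' @param minFraction minimum fraction of samples at or above the floor for
#'   a gene to survive (default 0.5).
#' @param topK number of most-variable genes to retain (default 5000).
#' @return list with \code{logcpm} (samples x surviving genes),
#'   \code{librarySize} (per-sample totals), and \code{kept} (gene names).
#' @export
preprocessExpression <- function(counts, genesInRows = FALSE, minLogCpm = 1,
                                 minFraction = 0.5, topK = 5000L) {
  counts <- as.matrix(counts)
  if (genesInRows) counts <- t(counts)
  lib <- rowSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with zero library size: ",
         paste(which(lib <= 0), collapse = ", "))
  logcpm <- log2(sweep(counts + 0.5, 1L, lib + 1, "/") * 1e6)
  passFrac <- colMeans(logcpm >= minLogCpm)
  keep <- passFrac >= minFraction
  logcpm <- logcpm[, keep, drop = FALSE]
  v <- apply(logcpm, 2L, stats::var)
  if (topK < ncol(logcpm)) {
    ord <- order(v, decreasing = TRUE)[seq_len(topK)]
    logcpm <- logcpm[, sort(ord), drop = FALSE]
  } else if (topK > ncol(logcpm)) {
    warning("topK (", topK, ") exceeds surviving genes (", ncol(logcpm),
            "); all retained")
  }
  list(logcpm = logcpm, librarySize = lib, kept = colnames(logcpm))
}

#' Read a delimited expression matrix
#'
#' First column is the sample (or gene) identifier; remaining columns are
#' numeric. Orientation is controlled by \code{genesInRows}.
#'
#' @param path TSV/CSV path (delimiter sniffed from the extension).
#' @param genesInRows TRUE when rows are genes.
#' @return numeric matrix, samples x genes.
#' @export
readExpression <- function(path, genesInRows = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  if (genesInRows) t(m) else m
}

#' Read a sample metadata table
#'
#' @param path TSV path with a \code{sample_id} column (or first column used
#'   as the key).
#' @return data.frame with rownames set to sample IDs.
#' @export
readMetadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  key <- if ("sample_id" %in% colnames(df)) "sample_id" else colnames(df)[1L]
  rownames(df) <- as.character(df[[key]])
  df
}

#' Run a differential co-expression study over a gene-set collection
#'
#' For each gene set: intersect members with the expression matrix, drop
#' sets below \code{minSetSize}, adjust for mean/variance effects, form
#' cross products, and run [kdcaTest()] (plus the eigengene comparator).
#' BH q-values are appended across all tested sets. Per-pathway seeds are
#' derived from the master seed and the pathway label, so results are
#' invariant to dispatch order and worker count.
#'
#' @param expression samples x genes numeric matrix (approximately normal
#'   scale, e.g. logCPM).
#' @param metadata data.frame with rownames (or \code{sample_id} column)
#'   matching the expression rownames.
#' @param geneSets a [GeneSetList-class] or named list of gene-ID vectors.
#' @param riskFactors character vector of metadata column name(s); a single
#'   non-numeric column is treated as categorical.
#' @param covariates,batch optional character vectors of metadata columns.
#' @param kernels,B,seed,refit,nu,center passed to [kdcaTest()].
#' @param varianceMode see [adjustPathway()].
#' @param minSetSize drop sets smaller than this after intersection
#'   (default 5).
#' @param eigengene also run the eigengene comparator (default TRUE).
#' @param workers parallel workers via \code{parallel::mclapply} (default 1).
#' @param fdrThresholds thresholds for the detections summary table.
#' @param outFile optional path; results written as TSV.
#' @return data.frame with one row per tested set: pathway, tested_size,
#'   per-kernel p, combined p, eigengene p, q-value; the detections-vs-FDR
#'   summary is attached as attribute \code{"detections"}.
#' @export
runStudy <- function(expression, metadata, geneSets, riskFactors,
                     covariates = NULL, batch = NULL,
                     kernels = c("linear", "projection", "gaussian"),
                     B = 1000L, seed = 1L, refit = TRUE,
                     varianceMode = "auto", nu = 1e-4, center = TRUE,
                     minSetSize = 5L, eigengene = TRUE, workers = 1L,
                     fdrThresholds = seq(0.05, 0.25, by = 0.05),
                     outFile = NULL) {
  expression <- as.matrix(expression)
  if (is(geneSets, "GeneSetList")) geneSets <- geneSets@sets
  missingCols <- setdiff(c(riskFactors, covariates, batch),
                         colnames(metadata))
  if (length(missingCols))
    stop("unknown metadata column(s): ", paste(missingCols, collapse = ", "))
  ids <- rownames(expression)
  if ("sample_id" %in% colnames(metadata))
    rownames(metadata) <- as.character(metadata$sample_id)
  hasMetaIds <- "sample_id" %in% colnames(metadata) ||
    .row_names_info(metadata) > 0   # explicit (non-automatic) rownames
  if (!is.null(ids) && hasMetaIds) {
    if (!all(ids %in% rownames(metadata)))
      stop("metadata is missing sample(s): ",
           paste(utils::head(setdiff(ids, rownames(metadata))), collapse = ", "))
    metadata <- metadata[ids, , drop = FALSE]
  } else if (nrow(metadata) != nrow(expression)) {
    stop("metadata and expression sample counts differ and no IDs to join on")
  }
  X <- if (length(riskFactors) == 1L &&
           !is.numeric(metadata[[riskFactors]]))
    factor(metadata[[riskFactors]])
  else
    as.matrix(metadata[, riskFactors, drop = FALSE])
  Cm <- if (is.null(covariates)) NULL else
    as.matrix(metadata[, covariates, drop = FALSE])
  Mm <- if (is.null(batch)) NULL else
    as.matrix(metadata[, batch, drop = FALSE])

  members <- lapply(geneSets, function(g) intersect(g, colnames(expression)))
  keep <- lengths(members) >= minSetSize
  dropped <- names(geneSets)[!keep]
  if (length(dropped))
    message(length(dropped), " set(s) below min size ", minSetSize,
            " dropped: ", paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  members <- members[keep]

  runOne <- function(nm) {
    genes <- members[[nm]]
    pseed <- deriveSeed(seed, nm)
    tryCatch({
      pd <- PathwayData(expression[, genes, drop = FALSE], X,
                        covariates = Cm, batch = Mm)
      res <- kdcaTest(pd, kernels = kernels, B = B, seed = pseed,
                      refit = refit, varianceMode = varianceMode, nu = nu,
                      center = center, eigengene = eigengene)
      row <- data.frame(pathway = nm, tested_size = length(genes),
                        stringsAsFactors = FALSE)
      for (k in kernels) row[[paste0("p_", k)]] <- res@pKernel[[k]]
      row$p_combined <- res@pCombined
      row$p_eigengene <- res@pEigengene
      row
    }, error = function(e) {
      warning("pathway '", nm, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  rows <- if (workers > 1L)
    parallel::mclapply(names(members), runOne, mc.cores = workers)
  else
    lapply(names(members), runOne)
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(pathway = character(0)))
  out <- do.call(rbind, rows)
  out$q_value <- bhFdr(out$p_combined)
  detections <- data.frame(
    fdr_threshold = fdrThresholds,
    kdca_combined = vapply(fdrThresholds,
                           function(t) sum(out$q_value <= t), 0L))
  if (eigengene)
    detections$eigengene <- vapply(fdrThresholds, function(t)
      sum(bhFdr(out$p_eigengene) <= t), 0L)
  attr(out, "detections") <- detections
  if (!is.null(outFile)) {
    utils::write.table(out, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
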