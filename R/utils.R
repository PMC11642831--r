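`%||%` <- function(a, b) if (is.null(a)) b else a

## Restore the caller's RNG state on exit so seeded functions do not
## perturb the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible per-pathway seed from a master seed and a label
#'
#' Combines a master seed with a polynomial hash of the pathway label so that
#' pathways can be dispatched across workers while remaining reproducible and
#' independent of dispatch order. Always below 2^31.
#'
#' @param master integer master seed.
#' @param label character label (e.g. pathway name).
#' @return integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(master %% 2147483647L), as.integer(h)) %%
               2147483647L)
}

## number of values in `nulls` that are >= each element of `x` (ties count)
countGreaterEqual <- function(x, nulls) {
  s <- sort(nulls)
  length(nulls) - findInterval(x, s, left.open = TRUE)
}

## column-mean-center a matrix
centerColumns <- function(M) {
  sweep(M, 2L, colMeans(M), "-")
}

## center and scale columns to unit (sample) variance; error on constants
standardizeColumns <- function(M, what = "column") {
  s <- apply(M, 2L, stats::sd)
  if (any(s < .Machine$double.eps^0.5))
    stop("zero-variance ", what, "(s): ",
         paste(which(s < .Machine$double.eps^0.5), collapse = ", "))
  sweep(centerColumns(M), 2L, s, "/")
}
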