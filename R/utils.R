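# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values into the unit interval
#' @param x numeric vector
#' @return `x` with values forced into \[0, 1\]
#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)

# Column-wise L2 norms of a matrix.
col_norms <- function(m) sqrt(colSums(m^2))

# Cosine similarities between each column of `m` and vector `v`.
# Zero-norm columns or a zero-norm `v` are an error: a cosine is undefined.
cosine_cols <- function(m, v) {
  nv <- sqrt(sum(v^2))
  nm <- col_norms(m)
  if (nv == 0 || any(nm == 0)) {
    stop("cosine similarity undefined for zero-norm profiles")
  }
  as.numeric(crossprod(m, v)) / (nm * nv)
}

# Full cosine similarity matrix between columns of `m` (genes x items).
cosine_matrix <- function(m) {
  nm <- col_norms(m)
  if (any(nm == 0)) stop("cosine similarity undefined for zero-norm profiles")
  crossprod(m) / tcrossprod(nm)
}

# Format a numeric value at 6 significant digits for TSV output; keeps
# integers and characters untouched.
format_num6 <- function(x) {
  if (is.double(x)) signif(x, 6L) else x
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state, so
# generators behave as pure functions of their arguments plus seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a global seed: a small multiplier
# scheme keeping results within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(
    cohorts = 11L, compendium = 23L, survival = 37L, protrusions = 41L,
    permutation = 53L, bootstrap = 67L, scoring = 71L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) * 101L + off) %% 2147483587L
}
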