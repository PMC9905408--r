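# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic operations route their randomness through this so
# results are pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Coerce a counts/expression input to dgCMatrix with dimnames, validating
# shape. Accepts base matrices and any Matrix class.
as_gene_spot_matrix <- function(x, what = "matrix") {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_invalid("%s must carry gene row names and spot column names", what)
  }
  if (anyDuplicated(rownames(x))) stop_invalid("%s has duplicated gene names", what)
  if (anyDuplicated(colnames(x))) stop_invalid("%s has duplicated spot names", what)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Sample-variance of each row of a (possibly sparse) matrix.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop_invalid("need at least 2 spots to compute variances")
  mu <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
}
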