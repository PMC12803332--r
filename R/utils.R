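# Internal helpers shared across modules.

# Run expr with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed on exit. No global state leaks.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

# Row-wise Euclidean norms of a matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# Numerically stable shifted softplus log(0.5 exp(x) + 0.5) and its derivative
ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
ssp_grad <- function(x) 1 / (1 + exp(-x))

# Add a row vector to every row of a matrix (fast sweep(m, 2, b, "+"))
addrow <- function(A, b) A + rep(b, each = nrow(A))

# Row-wise maximum of a matrix (few columns)
rowmax <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx
}

# Row-wise softmax of a matrix
softmax_rows <- function(m) {
  e <- exp(m - rowmax(m))
  e / rowSums(e)
}

# Scatter-add rows of `values` (n_items x k) into an (n_groups x k) matrix by
# integer group index. rowsum() drops empty groups, so re-expand explicitly.
scatter_add <- function(values, group, n_groups) {
  out <- matrix(0, n_groups, ncol(values))
  if (length(group) == 0L) return(out)
  rs <- rowsum(values, group = group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
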