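# Internal numerical helpers shared across modules.

# Numerical rank by singular values, relative threshold 1e-10 * sigma_max.
mat_rank <- function(M, rel_tol = 1e-10) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  s <- svd(M, nu = 0, nv = 0)$d
  if (length(s) == 0 || s[1] == 0) return(0L)
  sum(s > rel_tol * s[1])
}

# Moore-Penrose pseudo-inverse via SVD with the same relative threshold.
mat_pinv <- function(M, rel_tol = 1e-10) {
  if (nrow(M) == 0 || ncol(M) == 0) return(t(M))
  sv <- svd(M)
  pos <- sv$d > rel_tol * max(sv$d, 0)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Orthonormal basis of the null space of M (columns).
null_basis <- function(M, rel_tol = 1e-10) {
  n <- ncol(M)
  if (nrow(M) == 0) return(diag(n))
  sv <- svd(M, nu = 0, nv = n)
  r <- sum(sv$d > rel_tol * max(sv$d, 0))
  if (r >= n) return(matrix(0, n, 0))
  sv$v[, seq.int(r + 1, n), drop = FALSE]
}

# Orthonormal basis of the left null space of M (columns span {z : z'M = 0}).
left_null_basis <- function(M, rel_tol = 1e-10) {
  null_basis(t(M), rel_tol)
}

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's stream so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Drop numerically-zero entries in place.
clean_zeros <- function(x, tol = 1e-12) {
  x[abs(x) < tol] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
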