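# Internal numerical helpers shared across the filtering/smoothing code.

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Symmetrize and floor the eigenvalues of a covariance matrix.
# Floors at `floor_ev` (clamping tiny negative eigenvalues arising from
# round-off); keeps the matrix exactly symmetric.
sym_psd <- function(C, floor_ev = 1e-10) {
  C <- (C + t(C)) / 2
  if (nrow(C) == 1L) {
    C[1, 1] <- max(C[1, 1], floor_ev)
    return(C)
  }
  # fast path: already positive definite (chol succeeds)
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (ok) return(C)
  e <- eigen(C, symmetric = TRUE)
  v <- pmax(e$values, max(floor_ev, 1e-12))
  C <- e$vectors %*% (v * t(e$vectors))
  (C + t(C)) / 2
}

# Cholesky with automatic eigenvalue repair: assumes `C` symmetric; on
# failure (semidefinite / round-off indefinite) floors the spectrum and
# retries. Returns the upper-triangular factor.
chol_safe <- function(C, floor_ev = 1e-12) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  v <- pmax(e$values, max(floor_ev, 1e-12 * max(abs(e$values), 1)))
  chol(e$vectors %*% (v * t(e$vectors)))
}

# Cholesky-based log-determinant of a symmetric positive-definite matrix.
logdet_pd <- function(C) {
  2 * sum(log(diag(chol(C))))
}

# Solve C x = b for symmetric positive-definite C.
solve_pd <- function(C, b) {
  ch <- chol(C)
  backsolve(ch, forwardsolve(t(ch), b))
}

# Multivariate Gaussian log-density; `cov` must be PD.
dmvnorm_log <- function(x, mean, cov) {
  d <- length(mean)
  ch <- chol(cov)
  z <- forwardsolve(t(ch), x - mean)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dyntrf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
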