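# Exact rational linear algebra for stoichiometric matrices (small integer
# entries), plus floating-point nullspace helpers for sampling and reduction.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}
gcd_vec <- function(v) Reduce(gcd2, abs(v[v != 0]), accumulate = FALSE)
lcm2 <- function(a, b) if (a == 0 || b == 0) 0 else abs(a / gcd2(a, b) * b)

# Reduced row echelon form over the rationals, exact for integer input.
# Fractions are carried as numerator/denominator pairs in doubles; entries
# stay exact for the small integer stoichiometries this package handles.
rref_rational <- function(M) {
  m <- nrow(M); n <- ncol(M)
  num <- M
  den <- matrix(1, m, n)
  reduce <- function(i, j) {
    g <- gcd2(num[i, j], den[i, j])
    if (g > 0.5) { num[i, j] <<- num[i, j] / g; den[i, j] <<- den[i, j] / g }
    if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which(num[row:m, col] != 0)
    if (length(p) == 0L) next
    p <- p[1L] + row - 1L
    if (p != row) {
      num[c(row, p), ] <- num[c(p, row), ]
      den[c(row, p), ] <- den[c(p, row), ]
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(n)) {
      num[row, j] <- num[row, j] * pd
      den[row, j] <- den[row, j] * pn
      reduce(row, j)
    }
    # eliminate other rows
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(n)) {
        # a_ij <- a_ij - f * r_j
        nn <- num[i, j] * fd * den[row, j] - fn * num[row, j] * den[i, j]
        dd <- den[i, j] * fd * den[row, j]
        num[i, j] <- nn; den[i, j] <- dd
        reduce(i, j)
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

# Nullspace basis of an integer matrix, one vector per row, entries scaled
# to minimal integers with positive leading coefficient.
rational_nullspace <- function(M) {
  n <- ncol(M)
  if (n == 0L) return(matrix(0, 0, 0))
  if (nrow(M) == 0L) {
    return(diag(1, n))
  }
  r <- rref_rational(M)
  free <- setdiff(seq_len(n), r$pivots)
  B <- matrix(0, length(free), n)
  for (k in seq_along(free)) {
    fc <- free[k]
    v_num <- numeric(n); v_den <- rep(1, n)
    v_num[fc] <- 1
    for (i in seq_along(r$pivots)) {
      pc <- r$pivots[i]
      v_num[pc] <- -r$num[i, fc]
      v_den[pc] <- r$den[i, fc]
    }
    L <- Reduce(lcm2, v_den[v_num != 0], 1)
    v <- v_num * (L / v_den)
    g <- gcd_vec(v)
    if (!is.null(g) && length(g) && g > 0.5) v <- v / g
    lead <- v[v != 0][1L]
    if (!is.na(lead) && lead < 0) v <- -v
    B[k, ] <- v
  }
  B
}

# Orthonormal nullspace basis (floating point), columns span {x : Mx = 0}.
nullspace_basis <- function(M, tol = 1e-10) {
  if (ncol(M) == 0L) return(matrix(0, 0, 0))
  if (nrow(M) == 0L) return(diag(1, ncol(M)))
  sv <- svd(M, nu = 0, nv = ncol(M))
  d <- sv$d
  rank <- sum(d > tol * max(d, 1))
  if (rank == ncol(M)) return(matrix(0, ncol(M), 0))
  sv$v[, (rank + 1L):ncol(M), drop = FALSE]
}

# Orthonormal basis of the column space of M.
range_basis <- function(M, tol = 1e-10) {
  if (ncol(M) == 0L || nrow(M) == 0L) return(matrix(0, nrow(M), 0))
  sv <- svd(M)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  sv$u[, seq_len(rank), drop = FALSE]
}
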