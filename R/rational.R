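# Exact rational linear algebra (small matrices only).
#
# Loop grouping requires the *exact* null space of the internal
# stoichiometric matrix: floating-point null bases produce spurious supports.
# Entries are rationalised (denominator <= 1e6), and Gauss-Jordan elimination
# is carried out on numerator/denominator pairs held exactly in doubles.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

# continued-fraction rationalisation of a single number
rationalize1 <- function(x, max_den = 1e6, tol = 1e-9) {
  if (x == 0) return(c(0, 1))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    if (abs(p / q - x) < tol * max(1, x)) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(sign * p1, q1)
}

# Reduced row echelon form over the rationals; M given as numeric matrix.
# Returns list(num, den, pivots) with num/den the RREF fraction matrices.
rat_rref <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  N <- matrix(0, nr, nc); D <- matrix(1, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    f <- rationalize1(M[i, j]); N[i, j] <- f[1]; D[i, j] <- f[2]
  }
  red <- function(n, d) {
    if (n == 0) return(c(0, 1))
    g <- gcd2(n, d)
    s <- if (d < 0) -1 else 1
    c(s * n / g, s * d / g)
  }
  piv_rows <- integer(0); piv_cols <- integer(0)
  row <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    p <- which(N[row:nr, col] != 0)
    if (length(p) == 0) next
    p <- p[1] + row - 1
    if (p != row) { # swap
      tmp <- N[row, ]; N[row, ] <- N[p, ]; N[p, ] <- tmp
      tmp <- D[row, ]; D[row, ] <- D[p, ]; D[p, ] <- tmp
    }
    # normalise pivot row: divide by pivot fraction
    pn <- N[row, col]; pd <- D[row, col]
    for (j in seq_len(nc)) {
      f <- red(N[row, j] * pd, D[row, j] * pn)
      N[row, j] <- f[1]; D[row, j] <- f[2]
    }
    # eliminate all other rows
    for (i in seq_len(nr)) {
      if (i == row || N[i, col] == 0) next
      fn <- N[i, col]; fd <- D[i, col]
      for (j in seq_len(nc)) {
        # M[i,j] <- M[i,j] - f * M[row,j]
        an <- N[i, j]; ad <- D[i, j]
        bn <- fn * N[row, j]; bd <- fd * D[row, j]
        nn <- an * bd - bn * ad; nd <- ad * bd
        f2 <- red(nn, nd)
        N[i, j] <- f2[1]; D[i, j] <- f2[2]
      }
    }
    piv_rows <- c(piv_rows, row); piv_cols <- c(piv_cols, col)
    row <- row + 1
  }
  list(num = N, den = D, piv_rows = piv_rows, piv_cols = piv_cols)
}

#' Exact rational null-space basis
#'
#' @param M numeric matrix with rational entries.
#' @return matrix whose columns are integer-scaled null-space basis vectors
#'   (primitive: entries coprime, first non-zero entry positive); satisfies
#'   `M %*% basis == 0` exactly for rational inputs.
#' @export
rat_nullspace <- function(M) {
  nc <- ncol(M)
  if (nc == 0) return(matrix(0, 0, 0))
  r <- rat_rref(M)
  free_cols <- setdiff(seq_len(nc), r$piv_cols)
  if (length(free_cols) == 0) return(matrix(0, nc, 0))
  basis <- matrix(0, nc, length(free_cols))
  for (k in seq_along(free_cols)) {
    fc <- free_cols[[k]]
    # fractional solution: x_fc = 1, x_pivcol = -R[pivrow, fc]
    num <- rep(0, nc); den <- rep(1, nc)
    num[fc] <- 1
    for (t in seq_along(r$piv_cols)) {
      num[r$piv_cols[[t]]] <- -r$num[r$piv_rows[[t]], fc]
      den[r$piv_cols[[t]]] <- r$den[r$piv_rows[[t]], fc]
    }
    # clear denominators
    L <- 1
    for (d in unique(den)) L <- L * d / gcd2(L, d)
    v <- num * (L / den)
    g <- 0
    for (a in v) if (a != 0) g <- gcd2(g, a)
    if (g > 0) v <- v / g
    nz <- which(v != 0)[1]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    basis[, k] <- v
  }
  basis
}
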