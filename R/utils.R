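# Lattice helpers shared across solvers and agent rules.
# Matrices are indexed [row, col] on an n x n node-centered lattice.

# shift a matrix by (di, dj), replicating the boundary row/col (zero-Neumann
# mirror ghost nodes)
shift_mat <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + di, 1L), n)
  ci <- pmin(pmax(seq_len(p) + dj, 1L), p)
  m[ri, ci, drop = FALSE]
}

# central-difference gradient with one-sided boundaries; returns list(gx, gy)
# in 1/mm units (gx along columns/x, gy along rows/y)
grad_mat <- function(m, h) {
  n <- nrow(m); p <- ncol(m)
  gx <- (m[, c(2:p, p), drop = FALSE] - m[, c(1, 1:(p - 1)), drop = FALSE])
  gy <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE])
  divx <- matrix(2, n, p); divx[, c(1, p)] <- 1  # one-sided: spacing h not 2h

  divy <- matrix(2, n, p); divy[c(1, n), ] <- 1
  list(gx = gx / (divx * h), gy = gy / (divy * h))
}

grad_magnitude <- function(m, h) {
  g <- grad_mat(m, h)
  sqrt(g$gx^2 + g$gy^2)
}

# discrete 5-point Laplacian with mirrored (zero-Neumann) ghosts, applied to a
# matrix; returns sum over neighbors of (m_nb - m), NOT divided by h^2
laplace_mat <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

# Chebyshev dilation of a logical mask by `r` nodes
dilate_mask <- function(mask, r) {
  out <- mask
  if (r <= 0) return(out)
  for (k in seq_len(r)) {
    out <- out |
      shift_mat(out, 1, 0) | shift_mat(out, -1, 0) |
      shift_mat(out, 0, 1) | shift_mat(out, 0, -1) |
      shift_mat(out, 1, 1) | shift_mat(out, 1, -1) |
      shift_mat(out, -1, 1) | shift_mat(out, -1, -1)
  }
  out
}

# sparse zero-Neumann 5-point Laplacian operator (n*n x n*n), row sums zero,
# column-major node ordering; (L x)_i = sum_nb (x_nb - x_i)
neumann_laplacian <- function(n) {
  idx <- matrix(seq_len(n * n), n, n)
  i <- integer(0); j <- integer(0)
  pairs <- rbind(
    cbind(as.vector(idx[-n, ]), as.vector(idx[-1, ])),   # vertical neighbors
    cbind(as.vector(idx[, -n]), as.vector(idx[, -1]))    # horizontal neighbors
  )
  i <- c(pairs[, 1], pairs[, 2])
  j <- c(pairs[, 2], pairs[, 1])
  L <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n * n, n * n))
  deg <- Matrix::rowSums(L)
  L - Matrix::Diagonal(n * n, deg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919 * as.numeric(k)) %% 2147483647)
}
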