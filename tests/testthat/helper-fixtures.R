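# Shared fixtures: small configs and independent dense-matrix oracles.

tiny_config <- function(n = 31, t_end = 2, ...) {
  default_config(grid_nodes_per_side = n, t_end = t_end, ...)
}

# dense-matrix oracle for the screened-Poisson problem
# (diag(react) - D/h^2 L) u = rhs, zero-Neumann 5-point Laplacian, built
# entry-by-entry independently of the package's sparse assembly
dense_screened_solve <- function(react, rhs, D, h) {
  n <- nrow(rhs)
  N <- n * n
  A <- matrix(0, N, N)
  id <- function(i, j) (j - 1L) * n + i
  for (j in seq_len(n)) for (i in seq_len(n)) {
    k <- id(i, j)
    A[k, k] <- react[i, j]
    nbrs <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    for (nb in nbrs) {
      if (nb[1] >= 1 && nb[1] <= n && nb[2] >= 1 && nb[2] <= n) {
        A[k, k] <- A[k, k] + D / h^2
        A[k, id(nb[1], nb[2])] <- A[k, id(nb[1], nb[2])] - D / h^2
      }
      # out-of-range neighbor: mirrored ghost, no net contribution
    }
  }
  matrix(solve(A, as.vector(rhs)), n, n)
}

# scalar steady state of the ECM balance by bisection, independent of uniroot
ecm_steady_bisect <- function(lp, ld, m_star, k_p, k_d, lo = 0, hi = 1e5) {
  f <- function(E) lp / (1 + k_p * E) - ld * E * m_star / (1 + k_d * E)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# macrophage parameter block with overrides, detached from a full config
macro_params <- function(...) {
  p <- default_config(grid_nodes_per_side = 16)$macrophage
  ov <- list(...)
  p[names(ov)] <- ov
  p
}
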