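# Quasi-steady sparse reaction-diffusion solves and the Darcy
# pressure/velocity system. All operators use the 5-point Laplacian with
# mirrored ghost nodes (zero-Neumann boundaries); quantities live on an
# n x n node-centered lattice with spacing h (mm).

# generic screened-Poisson solve: (diag(react) - D/h^2 L) u = rhs,
# react >= 0 with at least one strictly positive entry
solve_screened <- function(react, rhs, D, h, what = "field") {
  n <- nrow(rhs)
  L <- neumann_laplacian(n)
  A <- Matrix::Diagonal(n * n, as.vector(react)) - (D / h^2) * L
  u <- tryCatch(
    as.vector(Matrix::solve(A, as.vector(rhs))),
    error = function(e) stop(sprintf("%s solve failed: %s", what,
                                     conditionMessage(e)), call. = FALSE)
  )
  res <- max(abs(as.vector(A %*% u) - as.vector(rhs)))
  if (!is.finite(res) || res > 1e-6 * max(1, max(abs(rhs)))) {
    stop(sprintf("%s solve did not converge (residual %.3g)", what, res),
         call. = FALSE)
  }
  matrix(u, n, n)
}

#' Quasi-steady oxygen field
#'
#' Solves `0 = div(D_sigma grad sigma) - lambda(region) sigma + lambda_ev`
#' with zero-Neumann boundaries, where the uptake rate depends on the tissue
#' region (normal tissue, proliferating tumor, hypoxic tumor, necrotic
#' debris) and the extravasation source `lambda_ev = s(x) (1 - sigma)` acts at
#' vessel nodes (see [oxygen_source()]). Oxygen is normalized to the vascular
#' concentration; the solution must lie in `[0, 1]` without clipping, and a
#' violation beyond solver tolerance raises a model-consistency error.
#'
#' @param region an integer region matrix (see [classify_regions()]).
#' @param network a `vessel_network`.
#' @param pressure interstitial pressure field.
#' @param oxygen_params the `oxygen` block of a [default_config()].
#' @param vessel_params the `vessel` block.
#' @param h node spacing (mm).
#' @return The oxygen matrix, values in `[0, 1]`.
#' @export
solve_oxygen <- function(region, network, pressure, oxygen_params,
                         vessel_params, h) {
  uptake <- matrix(oxygen_params$lambda_tissue, nrow(region), ncol(region))
  uptake[region == REGION_PROLIF] <- oxygen_params$lambda_tumor
  uptake[region == REGION_HYPOXIC] <- oxygen_params$q_sigma
  uptake[region == REGION_NECROTIC] <- oxygen_params$lambda_N
  s <- oxygen_supply_coef(network, pressure, vessel_params)
  if (all(s == 0)) return(matrix(0, nrow(region), ncol(region)))
  sigma <- solve_screened(uptake + s, s, oxygen_params$D_sigma, h, "oxygen")
  check_unit_interval(sigma, "oxygen")
  clamp(sigma, 0, 1)
}

#' Quasi-steady cytokine field
#'
#' Solves the steady mass balance
#' `0 = div(D_C grad C) + lambda_prod (1 - C) 1_region - lambda_circ 1_vessel C - lambda_decay C`
#' for one diffusible species (TNF-alpha, TGF-beta1, TAF, or the M2 growth
#' factor F). Production saturates as C approaches 1; washout into the
#' circulation acts at vessel nodes proportionally to C, preserving
#' non-negativity. The solution lies in `[0, 1]` by the maximum principle.
#'
#' @param spec a [cytokine_spec()].
#' @param production logical/0-1 matrix of production nodes (derived from the
#'   region map or the M2 agent positions per `spec$production_region`).
#' @param network a `vessel_network`.
#' @param h node spacing (mm).
#' @return The concentration matrix, values in `[0, 1]`.
#' @export
solve_cytokine <- function(spec, production, network, h) {
  prod_ind <- (production != 0) * 1
  if (all(prod_ind == 0)) return(matrix(0, nrow(production), ncol(production)))
  vess <- vessel_indicator(network)
  react <- spec$lambda_production * prod_ind +
    spec$lambda_circulation * vess + spec$lambda_decay
  rhs <- spec$lambda_production * prod_ind
  C <- solve_screened(react, rhs, spec$D_C, h, paste0("cytokine ", spec$name))
  check_unit_interval(C, spec$name)
  clamp(C, 0, 1)
}

check_unit_interval <- function(u, what, tol = 1e-7) {
  if (min(u) < -tol || max(u) > 1 + tol) {
    stop(sprintf("%s field violates [0,1] bounds (range %.4g..%.4g)",
                 what, min(u), max(u)), call. = FALSE)
  }
}

#' Darcy pressure and tissue velocity
#'
#' Tumor tissue advances through the surrounding tissue and ECM with velocity
#' `v_c = -mu grad P + chi_E grad E` (Darcy flow plus haptotaxis up ECM
#' gradients); assuming uniform tissue density, mass balance gives
#' `div v_c = lambda_p`. The pressure solves
#' `-div(mu grad P) = lambda_p - mean(lambda_p) - div(chi_E grad E)` with
#' zero-Neumann boundaries (the mean is removed for discrete compatibility)
#' and the zero-mean gauge. Velocities are returned on cell faces so that the
#' discrete divergence identity holds exactly, plus node-centered components
#' for the agent rules.
#'
#' @param lambda_p net proliferation-rate field (1/day).
#' @param E ECM density field.
#' @param mech the `mechanics` block (`mu`, `chi_E`).
#' @param h node spacing (mm).
#' @return List with `P` (zero-mean pressure), face velocities `vx`
#'   (n x (n-1)) and `vy` ((n-1) x n), and node-centered `vx_node`, `vy_node`
#'   (mm/day).
#' @export
solve_pressure_velocity <- function(lambda_p, E, mech, h) {
  n <- nrow(lambda_p)
  L <- neumann_laplacian(n)
  rhs <- as.vector(lambda_p) - mean(lambda_p) -
    (mech$chi_E / h^2) * as.vector(L %*% as.vector(E))
  A <- (-mech$mu / h^2) * L
  # gauge: pin node 1, rhs is compatible (zero mean) so the solution exists
  A[1, ] <- 0
  A[1, 1] <- 1
  rhs[1] <- 0
  P <- matrix(as.vector(Matrix::solve(A, rhs)), n, n)
  P <- P - mean(P)

  dPx <- (P[, -1, drop = FALSE] - P[, -n, drop = FALSE]) / h
  dPy <- (P[-1, , drop = FALSE] - P[-n, , drop = FALSE]) / h
  dEx <- (E[, -1, drop = FALSE] - E[, -n, drop = FALSE]) / h
  dEy <- (E[-1, , drop = FALSE] - E[-n, , drop = FALSE]) / h
  vx <- -mech$mu * dPx + mech$chi_E * dEx
  vy <- -mech$mu * dPy + mech$chi_E * dEy

  zx <- matrix(0, n, 1)
  vx_node <- (cbind(zx, vx) + cbind(vx, zx)) / 2
  zy <- matrix(0, 1, n)
  vy_node <- (rbind(zy, vy) + rbind(vy, zy)) / 2
  list(P = P, vx = vx, vy = vy, vx_node = vx_node, vy_node = vy_node)
}

# discrete divergence of face velocities (zero flux through the boundary)
velocity_divergence <- function(vx, vy, h) {
  n <- nrow(vx)
  zx <- matrix(0, n, 1)
  zy <- matrix(0, 1, n)
  (cbind(vx, zx) - cbind(zx, vx) + rbind(vy, zy) - rbind(zy, vy)) / h
}

#' Explicit step of the matrix-degrading-enzyme field
#'
#' MDEs (e.g. MMPs) are released by viable tumor tissue and by sprouting
#' capillary tips, diffuse, are consumed while degrading ECM, and decay:
#' `dM/dt = div(D_M grad M) + lambda_prod (1-M) 1_viable
#'  + lambda_sprout_prod (1-M) 1_tips - lambda_degr E M/(1 + k_d E)
#'  - lambda_decay M`.
#' The explicit Euler step is stable and bound-preserving for
#' `dt <= h^2 / (4 D_M)`; a larger step is a configuration error.
#'
#' @param M MDE field in `[0, 1]`.
#' @param viable logical/0-1 matrix of viable (proliferating or hypoxic)
#'   tumor nodes.
#' @param tips logical/0-1 matrix of active sprout-tip nodes.
#' @param E ECM density field (>= 0).
#' @param params the `mde` parameter block.
#' @param h node spacing (mm).
#' @param dt step (days).
#' @return Updated MDE matrix in `[0, 1]`.
#' @export
step_mde <- function(M, viable, tips, E, params, h, dt) {
  if (dt > h^2 / (4 * params$D_M)) {
    stop(sprintf("MDE step violates CFL bound: dt must be <= %.4g",
                 h^2 / (4 * params$D_M)), call. = FALSE)
  }
  dM <- (params$D_M / h^2) * laplace_mat(M) +
    params$lambda_production * (1 - M) * (viable != 0) +
    params$lambda_sprout_production * (1 - M) * (tips != 0) -
    params$lambda_degradation * E * M / (1 + params$k_d * E) -
    params$lambda_decay * M
  clamp(M + dt * dM, 0, 1)
}
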