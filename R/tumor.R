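# Tissue-region classification, the proliferation law with macrophage
# effects, ECM evolution, and the lattice interface advance.

#' Region codes
#'
#' Integer codes used in region matrices: 0 normal (non-cancerous) tissue,
#' 1 proliferating tumor, 2 hypoxic (quiescent) tumor, 3 necrotic tumor.
#' The tumor mask is the union of codes 1-3.
#'
#' @name region-codes
#' @export REGION_NORMAL REGION_PROLIF REGION_HYPOXIC REGION_NECROTIC
REGION_NORMAL <- 0L

#' @rdname region-codes
REGION_PROLIF <- 1L

#' @rdname region-codes
REGION_HYPOXIC <- 2L

#' @rdname region-codes
REGION_NECROTIC <- 3L

tumor_mask <- function(region) region != REGION_NORMAL
viable_mask <- function(region) {
  region == REGION_PROLIF | region == REGION_HYPOXIC
}

#' Classify tissue regions by oxygenation
#'
#' Within the tumor mask, a node is necrotic where oxygen has fallen below the
#' necrotic threshold, hypoxic (quiescent) where it lies between that
#' threshold and the local quiescence oxygen level, and proliferating where
#' oxygen meets or exceeds the quiescence level. Nodes outside the mask are
#' normal tissue. Necrosis is irreversible: a node necrotic in
#' `previous_region` stays necrotic regardless of recovered oxygen. The
#' hypoxic/proliferating boundary is reversible quiescence.
#'
#' @param sigma oxygen field in `[0, 1]`.
#' @param mask logical tumor-mask matrix.
#' @param q_ol_current local quiescence-threshold field (see
#'   [update_quiescence()]).
#' @param necrotic_threshold scalar oxygen level below which tissue necroses.
#' @param previous_region optional prior region matrix enforcing necrosis
#'   irreversibility.
#' @return Integer region matrix (see [region-codes]).
#' @export
classify_regions <- function(sigma, mask, q_ol_current, necrotic_threshold,
                             previous_region = NULL) {
  region <- matrix(REGION_NORMAL, nrow(sigma), ncol(sigma))
  region[mask & sigma >= q_ol_current] <- REGION_PROLIF
  region[mask & sigma < q_ol_current] <- REGION_HYPOXIC
  region[mask & sigma < necrotic_threshold] <- REGION_NECROTIC
  if (!is.null(previous_region)) {
    region[mask & previous_region == REGION_NECROTIC] <- REGION_NECROTIC
  }
  region
}

#' Net proliferation-rate field with macrophage effects
#'
#' Region-wise evaluation of the growth law: zero in normal tissue;
#' `(lambda_M + lambda_M2) sigma - (lambda_A + lambda_M1)` in the
#' proliferating region; `lambda_M2 sigma - (lambda_A + lambda_M1)` in the
#' hypoxic region (no native mitosis, but M2 growth factor still stimulates
#' and M1 NO still kills — cytotoxicity is cell-cycle independent); and
#' `-G_N` (debris degradation) in the necrotic region.
#'
#' @param region integer region matrix.
#' @param sigma oxygen field.
#' @param lambda_M1_field local M1 kill-rate field (see [m1_effect_field()]).
#' @param lambda_M2_rate local M2-driven proliferation-boost field (see
#'   [update_m2_rate()]).
#' @param tumor_params the `tumor` parameter block.
#' @return The `lambda_p` matrix (1/day).
#' @export
proliferation_field <- function(region, sigma, lambda_M1_field,
                                lambda_M2_rate, tumor_params) {
  lp <- matrix(0, nrow(region), ncol(region))
  pr <- region == REGION_PROLIF
  hy <- region == REGION_HYPOXIC
  lp[pr] <- (tumor_params$lambda_M + lambda_M2_rate[pr]) * sigma[pr] -
    (tumor_params$lambda_A + lambda_M1_field[pr])
  lp[hy] <- lambda_M2_rate[hy] * sigma[hy] -
    (tumor_params$lambda_A + lambda_M1_field[hy])
  lp[region == REGION_NECROTIC] <- -tumor_params$G_N
  lp
}

#' Update the M2-driven proliferation boost
#'
#' The diffusible M2 growth factor `F` raises the local proliferation rate
#' logistically toward the ceiling `lambda_M + lambda_M2 = 1`:
#' `d lambda_M2/dt = lambda_F F (1 - (lambda_M + lambda_M2))`, integrated with
#' one Euler step and clamped so the ceiling is never exceeded.
#'
#' @param lambda_M2 current boost field (>= 0).
#' @param F M2 growth-factor field in `[0, 1]`.
#' @param lambda_F effect rate of F on proliferation.
#' @param lambda_M native mitosis rate.
#' @param dt step (days).
#' @return Updated `lambda_M2` field, in `[0, 1 - lambda_M]`.
#' @export
update_m2_rate <- function(lambda_M2, F, lambda_F, lambda_M, dt) {
  out <- lambda_M2 + dt * lambda_F * F * (1 - (lambda_M + lambda_M2))
  clamp(out, 0, max(0, 1 - lambda_M))
}

#' Update the local quiescence oxygen threshold
#'
#' The M2 growth factor transiently lowers the viable (quiescence) oxygen
#' threshold, letting hypoxic tissue keep cycling; without F the threshold
#' recovers toward its standard value:
#' `dQ_OL/dt = lambda_OL (1 - F)(Qbar_OL - Q_OL) - lambda_OT F (Q_OL - Q_OL_min)`,
#' Euler-stepped and clamped to `[Q_OL_min, Qbar_OL]`.
#'
#' @param q_ol current threshold field.
#' @param F M2 growth-factor field in `[0, 1]`.
#' @param tumor_params the `tumor` parameter block (`lambda_OL`, `lambda_OT`,
#'   `Q_OL_bar`, `Q_OL_min`).
#' @param dt step (days).
#' @return Updated threshold field within `[Q_OL_min, Qbar_OL]`.
#' @export
update_quiescence <- function(q_ol, F, tumor_params, dt) {
  out <- q_ol + dt * (
    tumor_params$lambda_OL * (1 - F) * (tumor_params$Q_OL_bar - q_ol) -
      tumor_params$lambda_OT * F * (q_ol - tumor_params$Q_OL_min))
  clamp(out, tumor_params$Q_OL_min, tumor_params$Q_OL_bar)
}

#' Explicit step of the ECM density field
#'
#' ECM is deposited by viable tumor tissue and by sprouting capillary tips
#' (both self-limited by existing density through `1/(1 + k_p E)`) and is
#' degraded by MDEs through the saturating kinetics
#' `lambda_degr E M / (1 + k_d E)`:
#' `dE/dt = lambda_prod 1_viable/(1+k_p E) + lambda_sprout 1_tips/(1+k_p E)
#'  - lambda_degr E M/(1+k_d E)`. Density never goes negative.
#'
#' @param E ECM density field (>= 0).
#' @param M MDE field in `[0, 1]`.
#' @param viable logical/0-1 matrix of viable tumor nodes.
#' @param tips logical/0-1 matrix of sprout-tip nodes.
#' @param params the `ecm` parameter block.
#' @param dt step (days).
#' @return Updated ECM matrix (>= 0).
#' @export
step_ecm <- function(E, M, viable, tips, params, dt) {
  dE <- params$lambda_production * (viable != 0) / (1 + params$k_p * E) +
    params$lambda_sprout_production * (tips != 0) / (1 + params$k_p * E) -
    params$lambda_degradation * E * M / (1 + params$k_d * E)
  pmax(E + dt * dE, 0)
}

#' Advance or regress the tumor interface
#'
#' Growth: a normal node adjacent (4-neighborhood) to the tumor converts to
#' tumor with probability `min(1, v_n dt / h)` where `v_n` is the largest
#' outward face-velocity component from its tumor neighbors. Regression:
#' proliferating/hypoxic boundary nodes accumulate `lambda_p dt` as a
#' shrinkage debt; once the cumulative debt reaches -1 cell equivalent the
#' node reverts to normal. Necrotic nodes are permanent (debris is not
#' resorbed as free tissue), so necrotic area never decreases.
#'
#' @param region integer region matrix.
#' @param vel face-velocity list from [solve_pressure_velocity()].
#' @param lambda_p proliferation-rate field.
#' @param debt cumulative shrinkage-debt matrix (same shape), updated in the
#'   return value.
#' @param h node spacing (mm).
#' @param dt step (days).
#' @return List `region` (updated matrix) and `debt`.
#' @export
advance_tumor <- function(region, vel, lambda_p, debt, h, dt) {
  n <- nrow(region)
  mask <- tumor_mask(region)
  if (!any(mask)) return(list(region = region, debt = debt))

  # outward normal velocity seen by each normal node from tumor neighbors:
  # face velocity oriented tumor -> normal node
  zx <- matrix(0, n, 1); zy <- matrix(0, 1, n)
  vxl <- cbind(zx, vel$vx)   # face to the left of each node (flow +x into node)
  vxr <- cbind(vel$vx, zx)   # face to the right (flow -x into node)
  vyu <- rbind(zy, vel$vy)   # face above (flow +y into node)
  vyd <- rbind(vel$vy, zy)   # face below (flow -y into node)

  from_left <- shift_mat(mask, 0, -1) & !mask
  from_right <- shift_mat(mask, 0, 1) & !mask
  from_up <- shift_mat(mask, -1, 0) & !mask
  from_down <- shift_mat(mask, 1, 0) & !mask

  vn <- matrix(0, n, n)
  vn[from_left] <- pmax(vn[from_left], vxl[from_left])
  vn[from_right] <- pmax(vn[from_right], -vxr[from_right])
  vn[from_up] <- pmax(vn[from_up], vyu[from_up])
  vn[from_down] <- pmax(vn[from_down], -vyd[from_down])

  grow_candidates <- which(vn > 0 & !mask)
  if (length(grow_candidates)) {
    p <- pmin(1, vn[grow_candidates] * dt / h)
    converted <- grow_candidates[stats::runif(length(p)) < p]
    region[converted] <- REGION_PROLIF
    debt[converted] <- 0
  }

  # shrinkage bookkeeping on the (non-necrotic) tumor boundary; debt heals
  # toward zero at a fixed rate so only sustained mass loss removes tissue
  mask <- tumor_mask(region)
  interior <- mask & shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
    shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  boundary <- mask & !interior & region != REGION_NECROTIC
  heal <- 0.5
  debt[boundary] <- pmin(0, debt[boundary] * (1 - heal * dt) +
                           lambda_p[boundary] * dt)
  debt[!boundary] <- 0
  revert <- boundary & debt <= -1
  region[revert] <- REGION_NORMAL
  debt[revert] <- 0

  list(region = region, debt = debt)
}
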