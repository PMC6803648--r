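#' Build the pre-existing capillary grid
#'
#' The tissue panel is perfused by an evenly spaced rectilinear capillary
#' network. Metastatic cases use a strictly smaller line spacing than primary
#' cases, representing the densely vascularized hepatic environment.
#'
#' @param n lattice nodes per side.
#' @param line_spacing nodes between capillary lines.
#' @return A `vessel_network`: logical matrices `pre` and `neo`, a data frame
#'   of active sprout `tips` (`x` = column, `y` = row, `age`), a list of
#'   sprout segment node paths, and an anastomosis counter.
#' @export
build_vessel_grid <- function(n, line_spacing) {
  pre <- matrix(FALSE, n, n)
  # lines placed symmetrically about the domain center, so the central
  # capillary line always crosses the tumor seed regardless of spacing
  ctr <- as.integer(ceiling(n / 2))
  s <- as.integer(line_spacing)
  offs <- seq(0L, n, by = s)
  lines <- unique(pmin(pmax(c(ctr - rev(offs), ctr + offs), 1L), n))
  pre[lines, ] <- TRUE
  pre[, lines] <- TRUE
  network <- list(
    n = n,
    pre = pre,
    neo = matrix(FALSE, n, n),
    tips = data.frame(x = integer(0), y = integer(0), age = numeric(0),
                      seg = integer(0)),
    segments = list(),
    anastomoses = 0L
  )
  class(network) <- "vessel_network"
  network
}

#' Vessel characteristic function
#'
#' Binary indicator field equal to 1 exactly at vessel nodes (pre-existing
#' grid plus all neovascular sprout path nodes) and 0 elsewhere.
#'
#' @param network a `vessel_network`.
#' @return An integer 0/1 matrix of the lattice shape.
#' @export
vessel_indicator <- function(network) {
  ind <- network$pre | network$neo
  storage.mode(ind) <- "integer"
  ind
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("vessel_network: %d pre-existing nodes, %d neovascular nodes, %d active tips\n",
              sum(x$pre), sum(x$neo), nrow(x$tips)))
  invisible(x)
}

#' One angiogenesis step: TAF-driven sprouting
#'
#' Hypoxic tumor tissue releases tumor angiogenic factors (TAF) that diffuse
#' into the surrounding matrix and stimulate capillary sprouts from nearby
#' vessels. Vessel nodes where TAF exceeds `taf_sprout_threshold` launch a new
#' tip with probability `sprout_rate * dt`; active tips advance up the local
#' TAF gradient (4-neighborhood, with a small random perturbation) at
#' `tip_step` nodes/day, laying down neovascular nodes; a tip that comes
#' within `anastomosis_radius` of another vessel node connects and
#' deactivates. The vessel node set only ever grows.
#'
#' @param network a `vessel_network`.
#' @param taf TAF concentration field in `[0, 1]`.
#' @param params the `vessel` parameter block of a [default_config()].
#' @param dt step in days.
#' @return The updated `vessel_network`.
#' @export
sprout_step <- function(network, taf, params, dt) {
  n <- network$n
  existing <- network$pre | network$neo

  # launch new tips from eligible vessel nodes
  eligible <- which(existing & taf > params$taf_sprout_threshold &
                      !tip_occupied(network))
  if (length(eligible)) {
    p <- min(1, params$sprout_rate * dt)
    launch <- eligible[stats::runif(length(eligible)) < p]
    if (length(launch)) {
      rc <- arrayInd(launch, c(n, n))
      seg_ids <- length(network$segments) + seq_len(nrow(rc))
      network$tips <- rbind(network$tips,
                            data.frame(x = rc[, 2], y = rc[, 1], age = 0,
                                       seg = seg_ids))
      for (k in seq_len(nrow(rc))) {
        network$segments[[seg_ids[k]]] <- cbind(y = rc[k, 1], x = rc[k, 2])
      }
    }
  }

  if (!nrow(network$tips)) return(network)

  n_moves <- floor(params$tip_step * dt) +
    (stats::runif(nrow(network$tips)) < (params$tip_step * dt) %% 1)
  keep <- rep(TRUE, nrow(network$tips))
  for (k in seq_len(nrow(network$tips))) {
    x <- network$tips$x[k]; y <- network$tips$y[k]
    seg_id <- network$tips$seg[k]
    moves <- n_moves[k]
    while (moves > 0 && keep[k]) {
      nb <- rbind(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))
      ok <- nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      score <- taf[nb] + stats::rnorm(nrow(nb), sd = 0.02)
      pick <- nb[which.max(score), ]
      y <- pick[1]; x <- pick[2]
      network$neo[y, x] <- TRUE
      network$segments[[seg_id]] <- rbind(network$segments[[seg_id]],
                                          cbind(y = y, x = x))
      # anastomosis: connect if an unrelated vessel node lies within radius
      r <- params$anastomosis_radius
      y0 <- max(1, y - r); y1 <- min(n, y + r)
      x0 <- max(1, x - r); x1 <- min(n, x + r)
      nearby <- network$pre[y0:y1, x0:x1] |
        (network$neo[y0:y1, x0:x1] & !path_member(network$segments[[seg_id]],
                                                  y0:y1, x0:x1))
      if (any(nearby)) {
        keep[k] <- FALSE
        network$anastomoses <- network$anastomoses + 1L
      }
      moves <- moves - 1
    }
    network$tips$x[k] <- x
    network$tips$y[k] <- y
  }
  network$tips$age <- network$tips$age + dt
  network$tips <- network$tips[keep, , drop = FALSE]
  network
}

# logical matrix marking nodes currently occupied by an active tip
tip_occupied <- function(network) {
  occ <- matrix(FALSE, network$n, network$n)
  if (nrow(network$tips)) occ[cbind(network$tips$y, network$tips$x)] <- TRUE
  occ
}

# TRUE where the (y, x) window cells belong to the given segment path
path_member <- function(segment, ys, xs) {
  m <- matrix(FALSE, length(ys), length(xs))
  hit <- segment[, "y"] %in% ys & segment[, "x"] %in% xs
  if (any(hit)) {
    m[cbind(match(segment[hit, "y"], ys), match(segment[hit, "x"], xs))] <- TRUE
  }
  m
}

#' Oxygen extravasation source field
#'
#' Oxygen leaves the vasculature at vessel nodes at a rate set by the supply
#' rate of the vessel class (pre-existing vs. neovascular), the hematocrit,
#' the local oxygen deficit `(1 - sigma)`, and the interstitial pressure
#' relative to the effective perfusion pressure:
#' `lambda_ev = 1_vessel * lambda_supply * h * (1 - sigma) * max(0, 1 - P/P_eff)`.
#'
#' @param network a `vessel_network`.
#' @param pressure oncotic/interstitial pressure field.
#' @param sigma oxygen field in `[0, 1]`.
#' @param params the `vessel` parameter block.
#' @return The source field (same shape as `sigma`).
#' @export
oxygen_source <- function(network, pressure, sigma, params) {
  stopifnot(all(is.finite(pressure)), all(is.finite(sigma)))
  supply <- matrix(0, network$n, network$n)
  supply[network$pre] <- params$lambda_pre_sigma
  supply[network$neo & !network$pre] <- params$lambda_neo_sigma
  supply * params$hematocrit_h * (1 - sigma) *
    pmax(0, 1 - pressure / params$p_eff)
}

# supply-rate coefficient s(x) such that the extravasation term is s*(1-sigma);
# used to keep the oxygen solve linear in sigma
oxygen_supply_coef <- function(network, pressure, params) {
  supply <- matrix(0, network$n, network$n)
  supply[network$pre] <- params$lambda_pre_sigma
  supply[network$neo & !network$pre] <- params$lambda_neo_sigma
  supply * params$hematocrit_h * pmax(0, 1 - pressure / params$p_eff)
}
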