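# Discrete tumor-associated macrophage agents: extravasation from the
# vasculature, chemotactic migration, terminal M1/M2 polarization, and the
# NO-mediated M1 effector field.

#' Extravasate naive macrophages from the vasculature
#'
#' Each vessel node spawns a naive agent with probability
#' `extravasation_rate * |grad chemoattractant| * dt` (capped at 1); the
#' chemoattractant is the TAF field released by hypoxic tumor tissue, so
#' recruitment concentrates where its gradient is steep near the lesion.
#'
#' @param network a `vessel_network`.
#' @param chemoattractant field in `[0, 1]`.
#' @param params the `macrophage` parameter block.
#' @param h node spacing (mm); gradients are in 1/mm.
#' @param dt step (days).
#' @param next_id first id to assign.
#' @param exclude optional logical matrix of nodes whose vessels do not
#'   recruit (the simulation loop passes the tumor mask: monocytes enter from
#'   peritumoral vasculature, intratumoral vessels being co-opted).
#' @return Data frame of newly spawned agents (possibly empty).
#' @export
extravasate <- function(network, chemoattractant, params, h, dt,
                        next_id = 1L, exclude = NULL) {
  ind <- vessel_indicator(network)
  if (!is.null(exclude)) ind[exclude] <- 0L
  vess <- which(ind == 1)
  if (!length(vess)) return(empty_agents())
  gmag <- grad_magnitude(chemoattractant, h)
  p <- pmin(1, params$extravasation_rate * gmag[vess] * dt)
  spawn <- vess[stats::runif(length(vess)) < p]
  if (!length(spawn)) return(empty_agents())
  rc <- arrayInd(spawn, dim(chemoattractant))
  data.frame(id = next_id - 1L + seq_along(spawn),
             x = rc[, 2], y = rc[, 1],
             phenotype = "naive", age = 0,
             stringsAsFactors = FALSE)
}

#' M1 concentric bias field
#'
#' M1 macrophages migrate deeper into tumor tissue than M2; this is modeled
#' as a concentric field of unit value at the tumor centroid falling linearly
#' to zero at the lesion boundary (and zero outside), whose gradient biases
#' M1 movement toward the lesion center.
#'
#' @param region integer region matrix.
#' @return Matrix in `[0, 1]`.
#' @export
center_bias_field <- function(region) {
  mask <- tumor_mask(region)
  B <- matrix(0, nrow(region), ncol(region))
  if (!any(mask)) return(B)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  d <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  dmax <- max(d, 1e-9)
  B[mask] <- 1 - d / dmax
  B
}

#' Migrate macrophage agents
#'
#' Each agent takes up to `motility * dt` lattice steps (fractional part
#' resolved stochastically). Every step samples among the in-bounds
#' 4-neighbors with probability proportional to `exp(score)`, where
#' `score = w_chem dC - w_oxy dsigma - w_press dP + [M1] w_center dB`:
#' chemoattractant gradients attract, oxygen and pressure gradients repel
#' (interstitial drift toward hypoxic, low-pressure tissue), and polarized M1
#' agents are additionally biased toward the lesion center through the
#' concentric field `B`. Agents never leave the lattice.
#'
#' @param agents agent data frame.
#' @param chem,sigma,pressure,bias fields on the lattice.
#' @param params the `macrophage` parameter block.
#' @param dt step (days).
#' @return The agent data frame with updated positions and ages.
#' @export
migrate <- function(agents, chem, sigma, pressure, bias, params, dt) {
  if (!nrow(agents)) return(agents)
  n <- nrow(chem)
  steps <- floor(params$motility * dt) +
    (stats::runif(nrow(agents)) < (params$motility * dt) %% 1)
  max_steps <- max(steps)
  if (max_steps == 0) {
    agents$age <- agents$age + dt
    return(agents)
  }
  m1 <- agents$phenotype == "M1"
  for (s in seq_len(max_steps)) {
    act <- which(steps >= s)
    if (!length(act)) break
    x <- agents$x[act]; y <- agents$y[act]
    cur <- cbind(y, x)
    score_cur <- params$w_chem * chem[cur] - params$w_oxy * sigma[cur] -
      params$w_press * pressure[cur] +
      ifelse(m1[act], params$m1_center_bias_weight * bias[cur], 0)
    w <- matrix(0, length(act), 4)
    moves <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    for (d in 1:4) {
      ny <- y + moves[[d]][1]; nx <- x + moves[[d]][2]
      inb <- ny >= 1 & ny <= n & nx >= 1 & nx <= n
      ny2 <- pmin(pmax(ny, 1L), n); nx2 <- pmin(pmax(nx, 1L), n)
      nbi <- cbind(ny2, nx2)
      sc <- params$w_chem * chem[nbi] - params$w_oxy * sigma[nbi] -
        params$w_press * pressure[nbi] +
        ifelse(m1[act], params$m1_center_bias_weight * bias[nbi], 0)
      w[, d] <- ifelse(inb, exp(pmin(sc - score_cur, 50)), 0)
    }
    tot <- rowSums(w)
    u <- stats::runif(length(act)) * tot
    # choice = first direction whose cumulative weight reaches u
    cumw <- t(apply(w, 1, cumsum))
    choice <- max.col(cumw >= u, ties.method = "first")
    dy <- vapply(moves, `[`, integer(1), 1)[choice]
    dx <- vapply(moves, `[`, integer(1), 2)[choice]
    agents$y[act] <- pmin(pmax(y + dy, 1L), n)
    agents$x[act] <- pmin(pmax(x + dx, 1L), n)
  }
  agents$age <- agents$age + dt
  agents
}

#' Polarize naive macrophages
#'
#' Inside the tumor microenvironment (tumor mask plus a margin of
#' `microenv_margin` nodes) a naive agent commits, with probability
#' `polarization_prob * dt`, to the terminal phenotype whose cytokine exceeds
#' its threshold: TNF-alpha above `tnf_threshold` drives M1, TGF-beta1 above
#' `tgf_threshold` drives M2. If both exceed, the species with the larger
#' normalized excess `(c - theta)/theta` wins, ties going to M1. Polarization
#' is terminal: no M1/M2 interconversion or reversal ever occurs, and with
#' `polarization_enabled = FALSE` in the configuration the experiment loop
#' never calls this step.
#'
#' @param agents agent data frame.
#' @param c_tnf,c_tgf cytokine fields in `[0, 1]`.
#' @param microenv logical matrix of microenvironment nodes.
#' @param params the `macrophage` parameter block.
#' @param dt step (days).
#' @return The agent data frame with updated phenotypes.
#' @export
polarize <- function(agents, c_tnf, c_tgf, microenv, params, dt) {
  if (!nrow(agents)) return(agents)
  naive <- which(agents$phenotype == "naive")
  if (!length(naive)) return(agents)
  pos <- cbind(agents$y[naive], agents$x[naive])
  inside <- microenv[pos]
  tnf <- c_tnf[pos]; tgf <- c_tgf[pos]
  m1_el <- tnf >= params$tnf_threshold
  m2_el <- tgf >= params$tgf_threshold
  eligible <- inside & (m1_el | m2_el)
  fire <- eligible & stats::runif(length(naive)) < min(1, params$polarization_prob * dt)
  if (!any(fire)) return(agents)
  exc_tnf <- (tnf - params$tnf_threshold) / params$tnf_threshold
  exc_tgf <- (tgf - params$tgf_threshold) / params$tgf_threshold
  to_m1 <- fire & m1_el & (!m2_el | exc_tnf >= exc_tgf)
  to_m2 <- fire & m2_el & !to_m1
  agents$phenotype[naive[to_m1]] <- "M1"
  agents$phenotype[naive[to_m2]] <- "M2"
  agents
}

#' Single-agent polarization decision
#'
#' Contract-checked scalar form of [polarize()] for one naive agent at known
#' local cytokine levels (used by the unit tests and for clarity of the
#' decision rule). Calling it on a non-naive agent is an error.
#'
#' @param phenotype current phenotype (must be `"naive"`).
#' @param c_tnf_local,c_tgf_local local concentrations in `[0, 1]`.
#' @param params the `macrophage` parameter block.
#' @param dt step (days).
#' @return The (possibly unchanged) phenotype string.
#' @export
polarize_one <- function(phenotype, c_tnf_local, c_tgf_local, params, dt) {
  if (!identical(phenotype, "naive")) {
    stop("polarize called on a non-naive agent: phenotype is terminal",
         call. = FALSE)
  }
  m1_el <- c_tnf_local >= params$tnf_threshold
  m2_el <- c_tgf_local >= params$tgf_threshold
  if (!m1_el && !m2_el) return("naive")
  if (stats::runif(1) >= min(1, params$polarization_prob * dt)) return("naive")
  if (m1_el && m2_el) {
    exc_tnf <- (c_tnf_local - params$tnf_threshold) / params$tnf_threshold
    exc_tgf <- (c_tgf_local - params$tgf_threshold) / params$tgf_threshold
    if (exc_tnf >= exc_tgf) "M1" else "M2"
  } else if (m1_el) "M1" else "M2"
}

#' M1 cytotoxic effector field
#'
#' M1 macrophages kill tumor tissue through nitric-oxide release confined to
#' their immediate vicinity (NO is short-lived with a limited diffusion
#' distance): the field adds `lambda_NO` over every node within Chebyshev
#' radius `m1_neighborhood` of each M1 agent, additively across agents.
#'
#' @param agents agent data frame.
#' @param n lattice nodes per side.
#' @param params the `macrophage` parameter block.
#' @return The `lambda_M1` matrix.
#' @export
m1_effect_field <- function(agents, n, params) {
  field <- matrix(0, n, n)
  m1 <- agents[agents$phenotype == "M1", , drop = FALSE]
  if (!nrow(m1)) return(field)
  r <- params$m1_neighborhood
  for (k in seq_len(nrow(m1))) {
    y0 <- max(1, m1$y[k] - r); y1 <- min(n, m1$y[k] + r)
    x0 <- max(1, m1$x[k] - r); x1 <- min(n, m1$x[k] + r)
    field[y0:y1, x0:x1] <- field[y0:y1, x0:x1] + params$lambda_NO
  }
  field
}

#' Macrophage population fractions
#'
#' @param agents agent data frame.
#' @return Named numeric vector `(f_naive, f_M1, f_M2)` summing to 1, with an
#'   attribute `empty = TRUE` (and all-zero fractions) when no agents exist.
#' @export
population_fractions <- function(agents) {
  total <- nrow(agents)
  if (!total) {
    out <- c(f_naive = 0, f_M1 = 0, f_M2 = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- c(
    f_naive = sum(agents$phenotype == "naive") / total,
    f_M1 = sum(agents$phenotype == "M1") / total,
    f_M2 = sum(agents$phenotype == "M2") / total
  )
  attr(out, "empty") <- FALSE
  out
}

# indicator of nodes hosting at least one M2 agent (production region of the
# M2 growth factor F)
m2_node_indicator <- function(agents, n) {
  ind <- matrix(0, n, n)
  m2 <- agents[agents$phenotype == "M2", , drop = FALSE]
  if (nrow(m2)) ind[cbind(m2$y, m2$x)] <- 1
  ind
}
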