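#' Default simulation configuration
#'
#' Builds the full parameter set for one simulated case: a square 2D tissue
#' panel (side `domain_size_mm`) discretized on a regular lattice, a tumor
#' type (`primary` or `metastatic`), an ECM construct (`cECM`, control matrix,
#' or `tECM`, the transitional matrix after alcohol injury), and whether
#' macrophage polarization is enabled. All rates are per day; diffusivities
#' are in mm^2/day; concentrations (oxygen, cytokines, MDE) are dimensionless
#' in `[0, 1]` normalized to their vascular/saturation levels; ECM density is
#' dimensionless and O(1).
#'
#' The two tumor types differ in three calibrated respects: the metastatic
#' case has TNF-alpha production 10x the primary baseline (from the indirect
#' co-culture fold change), a denser pre-existing capillary grid (the highly
#' vascularized hepatic environment), and a lower necrotic threshold (hypoxic
#' rather than necrotic metastatic cores). The two ECM constructs differ in
#' far-field ECM density and in the production/degradation balance, with the
#' transitional matrix denser.
#'
#' @param tumor_type `"primary"` or `"metastatic"`.
#' @param ecm_type `"cECM"` or `"tECM"`.
#' @param polarization_enabled logical; if `FALSE` agents never leave the
#'   naive state (the "control" simulations).
#' @param grid_nodes_per_side lattice nodes per side (>= 16).
#' @param rng_seed integer seed controlling all stochastic elements
#'   (sprouting, extravasation, migration, polarization).
#' @param t_end simulated days (default 13).
#' @param dt time step in days.
#' @return A list of class `tam_config` with parameter blocks `tumor`,
#'   `mechanics`, `oxygen`, `cytokines` (one spec per diffusible species),
#'   `ecm`, `mde`, `macrophage`, `vessel`, plus the case selectors and grid
#'   geometry (`node_spacing` in mm).
#' @examples
#' cfg <- default_config(tumor_type = "metastatic", grid_nodes_per_side = 41)
#' cfg$node_spacing * (cfg$grid_nodes_per_side - 1)  # 2 mm panel
#' @export
default_config <- function(tumor_type = c("primary", "metastatic"),
                           ecm_type = c("cECM", "tECM"),
                           polarization_enabled = TRUE,
                           grid_nodes_per_side = 61,
                           rng_seed = 1L,
                           t_end = 13,
                           dt = 0.1) {
  tumor_type <- match.arg(tumor_type)
  ecm_type <- match.arg(ecm_type)
  n <- as.integer(grid_nodes_per_side)
  domain_size_mm <- 2
  h <- domain_size_mm / (n - 1)

  metastatic <- tumor_type == "metastatic"
  tecm <- ecm_type == "tECM"

  cfg <- list(
    grid_nodes_per_side = n,
    node_spacing = h,
    domain_size_mm = domain_size_mm,
    t_end = t_end,
    dt = dt,
    output_interval = 0.5,
    tumor_type = tumor_type,
    ecm_type = ecm_type,
    polarization_enabled = isTRUE(polarization_enabled),
    rng_seed = as.integer(rng_seed),
    seed_radius_nodes = 3,

    tumor = list(
      lambda_M = 0.8,          # native mitosis rate (1/day)
      lambda_A = 0.05,         # native apoptosis rate (1/day)
      G_N = 0.1,              # necrotic debris degradation rate
      Q_OL_bar = 0.45,         # standard quiescence oxygen threshold
      Q_OL_min = 0.25,         # lower bound of the quiescence threshold
      necrotic_threshold = if (metastatic) 0.13 else 0.22,
      lambda_OL = 1.0,         # quiescence threshold recovery rate
      lambda_OT = 1.0,         # M2 growth-factor threshold-lowering rate
      lambda_F = 1.5           # M2 growth-factor effect rate on proliferation
    ),
    mechanics = list(
      mu = 1.0,                # Darcy tissue mobility
      chi_E = 0.05             # haptotaxis coefficient
    ),
    oxygen = list(
      D_sigma = 0.04,
      lambda_tissue = 1.0,     # uptake outside tumor
      lambda_tumor = 10.0,      # uptake in proliferating region
      q_sigma = 3.0,           # uptake in hypoxic region (q_sigma <= lambda_tumor)
      lambda_N = 0.5           # decay in necrotic region
    ),
    cytokines = list(
      # TNF-alpha: short-ranged, secreted in the inflamed hypoxic core
      TNF = cytokine_spec("TNF", D_C = 0.02,
                          lambda_production = if (metastatic) 25 else 2.5,
                          lambda_circulation = 2.0, lambda_decay = 2.0,
                          production_region = "hypoxic_tumor"),
      # TGF-beta1: long-ranged and flat, secreted across the viable shell
      # and reaching well into the peritumoral margin
      TGFB1 = cytokine_spec("TGFB1", D_C = 0.15,
                            lambda_production = 1.8,
                            lambda_circulation = 1.0, lambda_decay = 0.8,
                            production_region = "viable_tumor"),
      TAF = cytokine_spec("TAF", D_C = 0.06,
                          lambda_production = 2.0,
                          lambda_circulation = 5.0, lambda_decay = 1.0,
                          production_region = "hypoxic_tumor"),
      F = cytokine_spec("F", D_C = 0.05,
                        lambda_production = 15.0,
                        lambda_circulation = 1.0, lambda_decay = 2.0,
                        production_region = "M2_agents")
    ),
    ecm = list(
      lambda_production = 0.3,
      lambda_sprout_production = 0.15,
      # degradation rates per construct: the transitional matrix keeps a lower
      # degradation/production ratio so its steady density is 1.5x control
      # (values from calibrate_ecm(1.5) with the default MDE fixed point 0.5)
      lambda_degradation = if (tecm) 1.0 else 1.5,
      k_p = 1.0,
      k_d = 1.0,
      E_far_cECM = 0.4,
      E_far_tECM = 0.6,
      E_far = if (tecm) 0.6 else 0.4
    ),
    mde = list(
      D_M = 8e-4,
      lambda_production = 1.0,
      lambda_sprout_production = 0.5,
      lambda_degradation = 0.5,
      lambda_decay = 1.0,
      k_d = 1.0
    ),
    macrophage = list(
      extravasation_rate = 1,    # per vessel node / day, scaled by |grad chem| (1/mm)
      motility = 20,             # lattice steps per day
      w_chem = 3,               # taxis weight on chemoattractant gradient (up)
      w_oxy = 4,                 # taxis weight on oxygen gradient (down)
      w_press = 2,               # taxis weight on pressure gradient (down)
      m1_center_bias_weight = 1, # M1 bias toward the lesion center
      tnf_threshold = 0.13,
      tgf_threshold = 0.12,
      polarization_prob = 1.1,   # per day once a threshold is exceeded
      lambda_NO = 0.006,         # M1 NO-mediated kill-rate contribution
      m1_neighborhood = 3,       # Chebyshev radius of the NO vicinity (nodes)
      microenv_margin = 8        # nodes beyond the tumor mask where agents polarize
    ),
    vessel = list(
      line_spacing_primary = max(2L, as.integer(round(0.5 / h))),
      line_spacing_metastatic = max(1L, as.integer(round(0.43 / h))),
      sprout_rate = 1.0,         # tip launches per eligible vessel node per day
      tip_step = 5,              # nodes per day along the TAF ascent
      taf_sprout_threshold = 0.1,
      anastomosis_radius = 1,
      lambda_pre_sigma = 28,     # oxygen supply rate, pre-existing vessels
      lambda_neo_sigma = 28,     # oxygen supply rate, sprouts
      hematocrit_h = 0.45,
      p_eff = 5                  # effective pressure scale for extravasation
    )
  )
  class(cfg) <- "tam_config"
  validate_config(cfg)
  cfg
}

#' Cytokine transport specification
#'
#' One diffusible species of the steady-state cytokine balance: diffusion,
#' saturating production on a production region, washout into the circulation
#' at vessel nodes, and first-order decay.
#'
#' @param name one of `"TNF"`, `"TGFB1"`, `"TAF"`, `"F"`.
#' @param D_C diffusivity (mm^2/day).
#' @param lambda_production,lambda_circulation,lambda_decay non-negative rates
#'   (1/day).
#' @param production_region `"viable_tumor"`, `"hypoxic_tumor"` or
#'   `"M2_agents"`.
#' @return A list of class `tam_cytokine_spec`.
#' @export
cytokine_spec <- function(name, D_C, lambda_production, lambda_circulation,
                          lambda_decay, production_region) {
  name <- match.arg(name, c("TNF", "TGFB1", "TAF", "F"))
  production_region <- match.arg(production_region,
                                 c("viable_tumor", "hypoxic_tumor", "M2_agents"))
  spec <- list(name = name, D_C = D_C,
               lambda_production = lambda_production,
               lambda_circulation = lambda_circulation,
               lambda_decay = lambda_decay,
               production_region = production_region)
  class(spec) <- "tam_cytokine_spec"
  spec
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [default_config()] object: grid size,
#' positive step sizes, non-negative rates, the ordering
#' `0 <= necrotic_threshold < Q_OL_min <= Q_OL_bar <= 1`, mitosis exceeding
#' apoptosis, denser metastatic vasculature, and the denser transitional ECM.
#' Errors name the offending field.
#'
#' @param config a `tam_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "tam_config")) {
    stop("config must be a 'tam_config' object", call. = FALSE)
  }
  if (is.na(config$grid_nodes_per_side) || config$grid_nodes_per_side < 16) {
    config_error("grid_nodes_per_side", "must be >= 16")
  }
  if (!isTRUE(config$dt > 0)) config_error("dt", "must be > 0")
  if (!isTRUE(config$t_end > 0)) config_error("t_end", "must be > 0")
  if (!isTRUE(config$node_spacing > 0)) config_error("node_spacing", "must be > 0")
  if (!config$tumor_type %in% c("primary", "metastatic")) {
    config_error("tumor_type", "must be 'primary' or 'metastatic'")
  }
  if (!config$ecm_type %in% c("cECM", "tECM")) {
    config_error("ecm_type", "must be 'cECM' or 'tECM'")
  }

  tp <- config$tumor
  if (!(tp$necrotic_threshold >= 0 && tp$necrotic_threshold < tp$Q_OL_min &&
        tp$Q_OL_min <= tp$Q_OL_bar && tp$Q_OL_bar <= 1)) {
    config_error("tumor", "need 0 <= necrotic_threshold < Q_OL_min <= Q_OL_bar <= 1")
  }
  if (!(tp$lambda_M > tp$lambda_A)) {
    config_error("tumor$lambda_M", "mitosis rate must exceed apoptosis rate")
  }
  if (!(config$mechanics$mu > 0)) config_error("mechanics$mu", "must be > 0")
  if (config$mechanics$chi_E < 0) config_error("mechanics$chi_E", "must be >= 0")
  if (config$oxygen$q_sigma > config$oxygen$lambda_tumor) {
    config_error("oxygen$q_sigma", "hypoxic uptake must not exceed proliferating uptake")
  }

  rate_blocks <- list(tumor = tp, oxygen = config$oxygen, ecm = config$ecm,
                      mde = config$mde, vessel = config$vessel)
  for (bn in names(rate_blocks)) {
    block <- rate_blocks[[bn]]
    num <- vapply(block, function(x) is.numeric(x) && length(x) == 1, logical(1))
    vals <- unlist(block[num])
    if (any(!is.finite(vals)) || any(vals < 0)) {
      bad <- names(vals)[!is.finite(vals) | vals < 0][1]
      config_error(paste0(bn, "$", bad), "must be a finite non-negative number")
    }
  }
  for (spec in config$cytokines) {
    rates <- c(spec$D_C, spec$lambda_production, spec$lambda_circulation,
               spec$lambda_decay)
    if (any(!is.finite(rates)) || any(rates < 0)) {
      config_error(paste0("cytokines$", spec$name), "rates must be finite and >= 0")
    }
  }
  vp <- config$vessel
  if (!(vp$line_spacing_metastatic < vp$line_spacing_primary)) {
    config_error("vessel$line_spacing_metastatic",
                 "metastatic vessel spacing must be smaller than primary")
  }
  if (vp$hematocrit_h < 0 || vp$hematocrit_h > 1) {
    config_error("vessel$hematocrit_h", "must lie in [0, 1]")
  }
  if (!(config$ecm$E_far_tECM > config$ecm$E_far_cECM)) {
    config_error("ecm$E_far_tECM", "transitional ECM must be denser than control")
  }
  mp <- config$macrophage
  if (mp$tnf_threshold <= 0 || mp$tnf_threshold >= 1 ||
      mp$tgf_threshold <= 0 || mp$tgf_threshold >= 1) {
    config_error("macrophage thresholds", "must lie in (0, 1)")
  }
  # explicit MDE step stability (4-point stencil CFL bound)
  if (config$dt > config$node_spacing^2 / (4 * config$mde$D_M)) {
    config_error("mde$D_M", sprintf(
      "explicit MDE step unstable: need dt <= h^2/(4 D_M) = %.4g",
      config$node_spacing^2 / (4 * config$mde$D_M)))
  }
  invisible(config)
}

#' @export
print.tam_config <- function(x, ...) {
  cat(sprintf("tamsim configuration: %s tumor on %s, polarization %s\n",
              x$tumor_type, x$ecm_type,
              if (x$polarization_enabled) "on" else "off"))
  cat(sprintf("  grid %dx%d (h = %.3g mm, %g mm panel), t_end = %g d, dt = %g d, seed %d\n",
              x$grid_nodes_per_side, x$grid_nodes_per_side, x$node_spacing,
              x$domain_size_mm, x$t_end, x$dt, x$rng_seed))
  invisible(x)
}

#' Read a configuration from a JSON file
#'
#' The file mirrors the `tam_config` field names exactly; fields absent from
#' the file keep their defaults for the selected case. Case selectors
#' (`tumor_type`, `ecm_type`, `polarization_enabled`, `rng_seed`) may be
#' overridden through the arguments, matching the command-line interface.
#'
#' @param path JSON file path.
#' @param ... overrides passed to [default_config()] (e.g. `tumor_type`).
#' @return A validated `tam_config`.
#' @export
read_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  sel <- c("tumor_type", "ecm_type", "polarization_enabled",
           "grid_nodes_per_side", "rng_seed", "t_end", "dt")
  base_args <- raw[intersect(names(raw), sel)]
  base_args[names(overrides)] <- overrides
  cfg <- do.call(default_config, base_args)
  for (nm in setdiff(names(raw), sel)) {
    if (!nm %in% names(cfg)) config_error(nm, "unknown configuration field")
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      unknown <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(unknown)) {
        config_error(paste0(nm, "$", unknown[1]), "unknown configuration field")
      }
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}
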