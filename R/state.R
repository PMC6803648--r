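#' Initialize the simulation state
#'
#' Seeds a small proliferating disc (radius `seed_radius_nodes`) at the domain
#' center, builds the pre-existing capillary grid for the case's tumor type,
#' initializes ECM at the construct's far-field density, performs one oxygen
#' solve to set the initial oxygenation, and classifies the initial regions.
#' No macrophage agents exist at t = 0. Deterministic: two builds from an
#' identical configuration (including `rng_seed`) are identical.
#'
#' @param config a validated [default_config()].
#' @return A list of class `tam_state`: `config`, `fields` (matrices `sigma`,
#'   `pressure`, `ecm`, `mde`, `c_tnf`, `c_tgf`, `taf`, `f_m2`, `lambda_p`,
#'   `lambda_m1`, `lambda_m2`, `q_ol`), `region` (integer matrix), `vessels`
#'   (a `vessel_network`), `agents` (data frame), `debt` (shrinkage
#'   bookkeeping), `time`, and `next_agent_id`.
#' @export
build_state <- function(config) {
  validate_config(config)
  n <- config$grid_nodes_per_side
  h <- config$node_spacing

  spacing <- if (config$tumor_type == "metastatic") {
    config$vessel$line_spacing_metastatic
  } else {
    config$vessel$line_spacing_primary
  }
  vessels <- build_vessel_grid(n, spacing)

  c0 <- (n + 1) / 2
  ii <- matrix(rep(seq_len(n), n), n, n)
  jj <- t(ii)
  mask <- if (config$seed_radius_nodes > 0) {
    (ii - c0)^2 + (jj - c0)^2 <= config$seed_radius_nodes^2
  } else {
    matrix(FALSE, n, n)
  }

  zero <- matrix(0, n, n)
  q_ol <- matrix(config$tumor$Q_OL_bar, n, n)
  region <- matrix(REGION_NORMAL, n, n)
  region[mask] <- REGION_PROLIF

  sigma <- solve_oxygen(region, vessels, zero, config$oxygen, config$vessel, h)
  region <- classify_regions(sigma, mask, q_ol, config$tumor$necrotic_threshold)

  state <- list(
    config = config,
    fields = list(
      sigma = sigma,
      pressure = zero,
      ecm = matrix(config$ecm$E_far, n, n),
      mde = zero,
      c_tnf = zero,
      c_tgf = zero,
      taf = zero,
      f_m2 = zero,
      lambda_p = zero,
      lambda_m1 = zero,
      lambda_m2 = zero,
      q_ol = q_ol
    ),
    region = region,
    vessels = vessels,
    agents = empty_agents(),
    debt = zero,
    time = 0,
    step_count = 0L,
    next_agent_id = 1L
  )
  class(state) <- "tam_state"
  state
}

empty_agents <- function() {
  data.frame(id = integer(0), x = integer(0), y = integer(0),
             phenotype = character(0), age = numeric(0),
             stringsAsFactors = FALSE)
}

#' Effective tumor radius from the region map
#'
#' The whole-lesion radius (necrotic core included) of the area-equivalent
#' circle: `sqrt(A / pi)` with `A = (# tumor-mask nodes) * spacing^2`. An
#' empty mask gives 0.
#'
#' @param region integer region matrix.
#' @param spacing node spacing (mm).
#' @return Radius in mm.
#' @export
tumor_radius <- function(region, spacing) {
  a <- sum(tumor_mask(region)) * spacing^2
  sqrt(a / pi)
}

#' @export
print.tam_state <- function(x, ...) {
  counts <- table(factor(x$region, levels = 0:3,
                         labels = c("normal", "proliferating", "hypoxic",
                                    "necrotic")))
  cat(sprintf("tamsim state at t = %.2f d (%s tumor, %s)\n", x$time,
              x$config$tumor_type, x$config$ecm_type))
  cat(sprintf("  radius %.3f mm | regions: %s\n",
              tumor_radius(x$region, x$config$node_spacing),
              paste(names(counts), counts, sep = "=", collapse = " ")))
  ph <- table(factor(x$agents$phenotype, levels = c("naive", "M1", "M2")))
  cat(sprintf("  agents: %d (naive=%d M1=%d M2=%d); vessels: pre=%d neo=%d\n",
              nrow(x$agents), ph[["naive"]], ph[["M1"]], ph[["M2"]],
              sum(x$vessels$pre), sum(x$vessels$neo)))
  invisible(x)
}
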