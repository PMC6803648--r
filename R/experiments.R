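# Orchestration of the simulation design: the composed time step, replicate
# runs per case, the eight-case design (2 tumor types x 2 ECM constructs x
# naive/polarized macrophages), and reporting.

#' One composed simulation step
#'
#' Advances the state by `dt` days in a fixed operator-splitting order:
#' (1) quasi-steady oxygen solve; (2) region classification (necrosis
#' irreversible); (3) quasi-steady cytokine solves (TAF, TNF-alpha,
#' TGF-beta1, M2 growth factor F); (4) angiogenic sprouting; (5) macrophage
#' extravasation, migration and (if enabled) polarization; (6) effector
#' updates (M1 NO field, M2 proliferation boost, quiescence threshold);
#' (7) explicit MDE and ECM steps; (8) proliferation field; (9) Darcy
#' pressure/velocity; (10) tumor interface advance. Quasi-steady fields are
#' solved before classification and agent decisions; deterministic given the
#' RNG state.
#'
#' @param state a `tam_state`.
#' @return The advanced `tam_state`.
#' @export
step_simulation <- function(state) {
  cfg <- state$config
  h <- cfg$node_spacing
  dt <- cfg$dt
  n <- cfg$grid_nodes_per_side
  f <- state$fields

  run_stage <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("step %d (t=%.2f d), stage '%s': %s", state$step_count + 1L,
                   state$time, stage, conditionMessage(e)), call. = FALSE)
    })
  }

  # (1) oxygen
  f$sigma <- run_stage(
    solve_oxygen(state$region, state$vessels, f$pressure, cfg$oxygen,
                 cfg$vessel, h), "oxygen")

  # (2) regions
  mask <- tumor_mask(state$region)
  state$region <- classify_regions(f$sigma, mask, f$q_ol,
                                   cfg$tumor$necrotic_threshold,
                                   previous_region = state$region)
  viable <- viable_mask(state$region)
  hypoxic <- state$region == REGION_HYPOXIC

  # (3) cytokines
  f$taf <- run_stage(
    solve_cytokine(cfg$cytokines$TAF, hypoxic, state$vessels, h), "TAF")
  f$c_tnf <- run_stage(
    solve_cytokine(cfg$cytokines$TNF, viable, state$vessels, h), "TNF")
  f$c_tgf <- run_stage(
    solve_cytokine(cfg$cytokines$TGFB1, viable, state$vessels, h), "TGF")
  f$f_m2 <- run_stage(
    solve_cytokine(cfg$cytokines$F, m2_node_indicator(state$agents, n),
                   state$vessels, h), "F")

  # (4) angiogenesis
  state$vessels <- run_stage(
    sprout_step(state$vessels, f$taf, cfg$vessel, dt), "sprouting")

  # (5) macrophages
  newborn <- run_stage(
    extravasate(state$vessels, f$taf, cfg$macrophage, h, dt,
                next_id = state$next_agent_id,
                exclude = tumor_mask(state$region)), "extravasation")
  if (nrow(newborn)) {
    state$next_agent_id <- state$next_agent_id + nrow(newborn)
    state$agents <- rbind(state$agents, newborn)
  }
  bias <- center_bias_field(state$region)
  state$agents <- run_stage(
    migrate(state$agents, f$taf, f$sigma, f$pressure, bias,
            cfg$macrophage, dt), "migration")
  if (cfg$polarization_enabled) {
    microenv <- dilate_mask(tumor_mask(state$region),
                            cfg$macrophage$microenv_margin)
    state$agents <- run_stage(
      polarize(state$agents, f$c_tnf, f$c_tgf, microenv, cfg$macrophage, dt),
      "polarization")
  }

  # (6) effectors
  f$lambda_m1 <- m1_effect_field(state$agents, n, cfg$macrophage)
  f$lambda_m2 <- update_m2_rate(f$lambda_m2, f$f_m2, cfg$tumor$lambda_F,
                                cfg$tumor$lambda_M, dt)
  f$q_ol <- update_quiescence(f$q_ol, f$f_m2, cfg$tumor, dt)

  # (7) MDE and ECM
  tips <- tip_occupied(state$vessels)
  f$mde <- run_stage(
    step_mde(f$mde, viable, tips, f$ecm, cfg$mde, h, dt), "MDE")
  f$ecm <- step_ecm(f$ecm, f$mde, viable, tips, cfg$ecm, dt)

  # (8) proliferation
  f$lambda_p <- proliferation_field(state$region, f$sigma, f$lambda_m1,
                                    f$lambda_m2, cfg$tumor)

  # (9) pressure / velocity
  vel <- run_stage(
    solve_pressure_velocity(f$lambda_p, f$ecm, cfg$mechanics, h), "pressure")
  f$pressure <- vel$P

  # (10) interface advance
  adv <- advance_tumor(state$region, vel, f$lambda_p, state$debt, h, dt)
  state$region <- adv$region
  state$debt <- adv$debt

  state$fields <- f
  state$velocity <- vel
  state$time <- state$time + dt
  state$step_count <- state$step_count + 1L
  state
}

#' Run one simulation to completion
#'
#' Seeds the RNG from `config$rng_seed`, builds the initial state, and steps
#' to `t_end`, sampling the tumor radius, macrophage population fractions,
#' and mean ECM density every `output_interval` days.
#'
#' @param config a [default_config()].
#' @param keep_state if `TRUE` (default) the final `tam_state` is attached.
#' @return A list of class `tam_run`: `config`, `series` (data frame with
#'   columns `day`, `radius_mm`, `n_agents`, `f_naive`, `f_M1`, `f_M2`,
#'   `ecm_mean`, `necrotic_nodes`), and `final` (the end state).
#' @export
run_simulation <- function(config, keep_state = TRUE) {
  validate_config(config)
  set.seed(config$rng_seed)
  state <- build_state(config)
  n_steps <- ceiling(config$t_end / config$dt - 1e-9)
  record_every <- max(1L, as.integer(round(config$output_interval / config$dt)))

  rows <- vector("list", n_steps %/% record_every + 2L)
  rows[[1]] <- run_series_row(state)
  ri <- 2L
  for (k in seq_len(n_steps)) {
    state <- step_simulation(state)
    if (k %% record_every == 0L || k == n_steps) {
      rows[[ri]] <- run_series_row(state)
      ri <- ri + 1L
    }
  }
  series <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  series <- series[!duplicated(series$day), , drop = FALSE]
  rownames(series) <- NULL
  out <- list(config = config, series = series,
              final = if (keep_state) state else NULL)
  class(out) <- "tam_run"
  out
}

run_series_row <- function(state) {
  fr <- population_fractions(state$agents)
  data.frame(
    day = state$time,
    radius_mm = tumor_radius(state$region, state$config$node_spacing),
    n_agents = nrow(state$agents),
    f_naive = fr[["f_naive"]],
    f_M1 = fr[["f_M1"]],
    f_M2 = fr[["f_M2"]],
    ecm_mean = mean(state$fields$ecm),
    necrotic_nodes = sum(state$region == REGION_NECROTIC)
  )
}

#' @export
print.tam_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf(paste0("tamsim run: %s/%s, polarization %s, seed %d\n",
                     "  day %.1f: radius %.3f mm, %d agents ",
                     "(naive %.0f%%, M1 %.0f%%, M2 %.0f%%)\n"),
              x$config$tumor_type, x$config$ecm_type,
              if (x$config$polarization_enabled) "on" else "off",
              x$config$rng_seed, last$day, last$radius_mm, last$n_agents,
              100 * last$f_naive, 100 * last$f_M1, 100 * last$f_M2))
  invisible(x)
}

#' Define one simulation case
#'
#' @param tumor_type,ecm_type,polarization_enabled case selectors.
#' @param seeds integer vector of replicate seeds (n_replicates = length).
#' @return A list of class `tam_case`.
#' @export
case_spec <- function(tumor_type, ecm_type, polarization_enabled,
                      seeds = c(101L, 202L, 303L)) {
  stopifnot(length(seeds) >= 1)
  out <- list(tumor_type = tumor_type, ecm_type = ecm_type,
              polarization_enabled = polarization_enabled,
              n_replicates = length(seeds), seeds = as.integer(seeds))
  class(out) <- "tam_case"
  out
}

#' Run one case over its replicate seeds
#'
#' @param case a [case_spec()].
#' @param grid_nodes_per_side lattice size for all replicates.
#' @param t_end simulated days.
#' @param keep_states keep final states in the per-replicate results.
#' @param ... further overrides passed to [default_config()].
#' @return A list of class `tam_case_result` with `case`, `runs` (one
#'   `tam_run` per seed) and `summary` (mean and SD of the final radius and
#'   final population fractions).
#' @export
run_case <- function(case, grid_nodes_per_side = 61, t_end = 13,
                     keep_states = FALSE, ...) {
  runs <- lapply(case$seeds, function(s) {
    cfg <- default_config(tumor_type = case$tumor_type,
                          ecm_type = case$ecm_type,
                          polarization_enabled = case$polarization_enabled,
                          grid_nodes_per_side = grid_nodes_per_side,
                          rng_seed = s, t_end = t_end, ...)
    tryCatch(run_simulation(cfg, keep_state = keep_states),
             error = function(e) {
               stop(sprintf("replicate with seed %d failed: %s", s,
                            conditionMessage(e)), call. = FALSE)
             })
  })
  finals <- do.call(rbind, lapply(runs, function(r) {
    r$series[nrow(r$series), ]
  }))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  summary <- data.frame(
    tumor_type = case$tumor_type, ecm_type = case$ecm_type,
    polarized = case$polarization_enabled,
    n = nrow(finals),
    radius_mean = mean(finals$radius_mm), radius_sd = sd0(finals$radius_mm),
    f_naive_mean = mean(finals$f_naive),
    f_M1_mean = mean(finals$f_M1), f_M1_sd = sd0(finals$f_M1),
    f_M2_mean = mean(finals$f_M2), f_M2_sd = sd0(finals$f_M2)
  )
  out <- list(case = case, runs = runs, finals = finals, summary = summary)
  class(out) <- "tam_case_result"
  out
}

#' Percent radius difference between primary and metastatic means
#'
#' `100 (r_primary - r_metastatic) / r_primary`: the percent by which the
#' metastatic lesion is smaller than the primary one.
#'
#' @param primary_mean,metastatic_mean mean final radii (mm).
#' @return Percent difference.
#' @export
percent_radius_difference <- function(primary_mean, metastatic_mean) {
  if (!is.finite(primary_mean) || primary_mean <= 0) {
    stop("primary_mean must be positive", call. = FALSE)
  }
  100 * (primary_mean - metastatic_mean) / primary_mean
}

#' Run the full eight-case simulation design
#'
#' Two tumor types x two ECM constructs, each with naive-only and with
#' polarized macrophages, at `n = length(seeds)` replicates per case.
#'
#' @param seeds replicate seeds used in every case.
#' @param grid_nodes_per_side lattice size.
#' @param t_end simulated days.
#' @param cases optional subset: data frame with columns `tumor_type`,
#'   `ecm_type`, `polarized`; default all eight.
#' @return A list of class `tam_design_result`: `results` (one
#'   `tam_case_result` per case) and `summary` (one aggregate row per case,
#'   plus percent radius differences between polarized primary and metastatic
#'   cases per ECM construct in `radius_differences`).
#' @export
run_design <- function(seeds = c(101L, 202L, 303L), grid_nodes_per_side = 61,
                       t_end = 13, cases = NULL) {
  if (is.null(cases)) {
    cases <- expand.grid(tumor_type = c("primary", "metastatic"),
                         ecm_type = c("cECM", "tECM"),
                         polarized = c(FALSE, TRUE),
                         stringsAsFactors = FALSE)
  }
  results <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    results[[i]] <- run_case(
      case_spec(cases$tumor_type[i], cases$ecm_type[i], cases$polarized[i],
                seeds = seeds),
      grid_nodes_per_side = grid_nodes_per_side, t_end = t_end)
  }
  summary <- do.call(rbind, lapply(results, function(r) r$summary))
  rownames(summary) <- NULL

  rd <- NULL
  for (ecm in unique(summary$ecm_type)) {
    pr <- summary[summary$polarized & summary$ecm_type == ecm &
                    summary$tumor_type == "primary", ]
    mt <- summary[summary$polarized & summary$ecm_type == ecm &
                    summary$tumor_type == "metastatic", ]
    if (nrow(pr) == 1 && nrow(mt) == 1) {
      rd <- rbind(rd, data.frame(
        ecm_type = ecm,
        percent_smaller = percent_radius_difference(pr$radius_mean,
                                                    mt$radius_mean)))
    }
  }
  out <- list(results = results, summary = summary, radius_differences = rd)
  class(out) <- "tam_design_result"
  out
}

#' Write run reports
#'
#' Writes, under `dir`: `summary.csv` (one aggregate row per case and one row
#' per replicate), per-case time-series CSVs, region heat-map PNG panels for
#' the cases whose final states were kept, and a machine-readable
#' `manifest.json` (seeds, grid, package version).
#'
#' @param design a `tam_design_result` (or list of `tam_case_result`).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
report <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  results <- if (inherits(design, "tam_design_result")) design$results else design
  files <- character(0)

  if (!length(results)) {
    warning("no results to report; writing manifest only")
  } else {
    replicate_rows <- do.call(rbind, lapply(results, function(r) {
      cbind(tumor_type = r$case$tumor_type, ecm_type = r$case$ecm_type,
            polarized = r$case$polarization_enabled, seed = r$case$seeds,
            r$finals)
    }))
    aggregate_rows <- do.call(rbind, lapply(results, function(r) r$summary))
    f <- file.path(dir, "summary.csv")
    utils::write.csv(aggregate_rows, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "replicates.csv")
    utils::write.csv(replicate_rows, f, row.names = FALSE)
    files <- c(files, f)
    if (inherits(design, "tam_design_result") &&
        !is.null(design$radius_differences)) {
      f <- file.path(dir, "radius_differences.csv")
      utils::write.csv(design$radius_differences, f, row.names = FALSE)
      files <- c(files, f)
    }
    for (r in results) {
      tag <- sprintf("%s_%s_%s", r$case$tumor_type, r$case$ecm_type,
                     if (r$case$polarization_enabled) "polarized" else "naive")
      f <- file.path(dir, sprintf("series_%s.csv", tag))
      series <- do.call(rbind, lapply(seq_along(r$runs), function(i) {
        cbind(seed = r$case$seeds[i], r$runs[[i]]$series)
      }))
      utils::write.csv(series, f, row.names = FALSE)
      files <- c(files, f)
      final <- r$runs[[1]]$final
      if (!is.null(final)) {
        f <- file.path(dir, sprintf("panels_%s.png", tag))
        grDevices::png(f, width = 900, height = 900)
        plot_state_panels(final)
        grDevices::dev.off()
        files <- c(files, f)
      }
    }
  }

  manifest <- list(
    package = "tamsim",
    version = as.character(utils::packageVersion("tamsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    cases = lapply(results, function(r) r$case[c("tumor_type", "ecm_type",
                                                 "polarization_enabled",
                                                 "seeds")])
  )
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Plot the 3x3 field panel layout for a state
#'
#' A 3x3 overview of one state: regions with
#' vessels, TNF-alpha, TGF-beta1 (top row); naive, M1, M2 agent density
#' (middle row); TAF, oxygen, ECM (bottom row).
#'
#' @param state a `tam_state`.
#' @return Invisibly `NULL`.
#' @export
plot_state_panels <- function(state) {
  op <- graphics::par(mfrow = c(3, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  n <- state$config$grid_nodes_per_side
  img <- function(m, main, col = grDevices::hcl.colors(64, "YlOrRd",
                                                       rev = TRUE)) {
    graphics::image(t(m)[, n:1], main = main, axes = FALSE, col = col)
  }
  reg <- state$region
  reg[vessel_indicator(state$vessels) == 1 & reg == REGION_NORMAL] <- 4L
  img(reg, "regions + vessels",
      col = c("white", "red", "blue", "brown4", "tan3"))
  img(state$fields$c_tnf, "TNF-alpha")
  img(state$fields$c_tgf, "TGF-beta1")
  dens <- function(ph) {
    d <- matrix(0, n, n)
    a <- state$agents[state$agents$phenotype == ph, , drop = FALSE]
    if (nrow(a)) for (k in seq_len(nrow(a))) {
      d[a$y[k], a$x[k]] <- d[a$y[k], a$x[k]] + 1
    }
    d
  }
  img(dens("naive"), "naive macrophages")
  img(dens("M1"), "M1 macrophages")
  img(dens("M2"), "M2 macrophages")
  img(state$fields$taf, "TAF")
  img(state$fields$sigma, "oxygen")
  img(state$fields$ecm, "ECM")
  invisible(NULL)
}
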