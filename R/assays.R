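# Synthetic indirect co-culture readouts (ELISA fold structure, transwell
# migration normalization) and the calibration mapping from readouts to
# simulation rates. These stand in for the wet-lab inputs of the analysis
# pipeline; absolute units are arbitrary because only ratios enter the model.

elisa_conditions <- function() {
  expand.grid(macrophage_state = c("naive", "M1", "M2"),
              tumor = c("none", "primary", "metastatic"),
              stringsAsFactors = FALSE)
}

#' Generate synthetic co-culture ELISA panels
#'
#' Emulates the indirect transwell co-culture readouts of TNF-alpha and
#' TGF-beta1 for macrophage state (naive/M1/M2) crossed with tumor condition
#' (none/primary/metastatic). The mean structure encodes the observed fold
#' changes: TNF-alpha is `m1_m2_fold` (default 5) times higher with M1 than
#' with M2 within every tumor condition, and the metastatic co-culture with
#' M1 is `met_primary_fold` (default 10) times the primary one; TGF-beta1 is
#' flat across conditions except a slight (default 1.2x, at most 1.3x)
#' elevation for primary cells with M1. Replicates carry lognormal noise with
#' coefficient of variation `noise_cv`.
#'
#' @param noise_cv coefficient of variation in `[0, 0.5]`.
#' @param n_replicates replicates per condition (>= 3).
#' @param m1_m2_fold,met_primary_fold,tgf_primary_m1_fold configurable fold
#'   structure.
#' @return Data frame of class `tam_elisa` with one row per condition x
#'   replicate: `macrophage_state`, `tumor`, `replicate`, `tnf_level`,
#'   `tgf_level`, plus the noiseless means `tnf_mean`, `tgf_mean`.
#' @export
generate_elisa <- function(noise_cv = 0.2, n_replicates = 6,
                           m1_m2_fold = 5, met_primary_fold = 10,
                           tgf_primary_m1_fold = 1.2) {
  stopifnot(noise_cv >= 0, noise_cv <= 0.5, n_replicates >= 3,
            tgf_primary_m1_fold <= 1.3)
  cond <- elisa_conditions()
  base_tnf <- 20   # arbitrary pg/mL-like units
  base_tgf <- 100

  tnf_mean <- numeric(nrow(cond))
  tgf_mean <- numeric(nrow(cond))
  for (i in seq_len(nrow(cond))) {
    tumor_scale <- switch(cond$tumor[i], none = 0.5, primary = 1,
                          metastatic = met_primary_fold)
    state_scale <- switch(cond$macrophage_state[i],
                          naive = 1, M2 = 1, M1 = m1_m2_fold)
    tnf_mean[i] <- base_tnf * tumor_scale * state_scale
    tgf_mean[i] <- base_tgf *
      if (cond$tumor[i] == "primary" && cond$macrophage_state[i] == "M1") {
        tgf_primary_m1_fold
      } else 1
  }

  rep_rows <- cond[rep(seq_len(nrow(cond)), each = n_replicates), ]
  rep_rows$replicate <- rep(seq_len(n_replicates), nrow(cond))
  mu_tnf <- rep(tnf_mean, each = n_replicates)
  mu_tgf <- rep(tgf_mean, each = n_replicates)
  if (noise_cv > 0) {
    s2 <- log(1 + noise_cv^2)
    draw <- function(mu) stats::rlnorm(length(mu), log(mu) - s2 / 2, sqrt(s2))
    rep_rows$tnf_level <- draw(mu_tnf)
    rep_rows$tgf_level <- draw(mu_tgf)
  } else {
    rep_rows$tnf_level <- mu_tnf
    rep_rows$tgf_level <- mu_tgf
  }
  rep_rows$tnf_mean <- mu_tnf
  rep_rows$tgf_mean <- mu_tgf
  rownames(rep_rows) <- NULL
  class(rep_rows) <- c("tam_elisa", "data.frame")
  rep_rows
}

panel_mean <- function(panels, state, tumor, what) {
  sel <- panels$macrophage_state == state & panels$tumor == tumor
  if (!any(sel)) {
    stop(sprintf("calibration error: missing ELISA condition %s x %s",
                 state, tumor), call. = FALSE)
  }
  mean(panels[[what]][sel])
}

#' Calibrate cytokine production rates from ELISA panels
#'
#' Maps the co-culture fold structure onto the cytokine production rates of
#' the simulation: the metastatic TNF-alpha rate is the primary baseline
#' scaled by the measured metastatic/primary fold with M1 macrophages; the
#' TGF-beta1 rate is shared by both tumor types (anchored by the geometric
#' mean, across tumor types, of the M2-row TGF level relative to the
#' no-tumor control, which is 1 for flat panels).
#'
#' @param panels a `tam_elisa` data frame covering at least the M1/M2 states
#'   for both tumor conditions.
#' @param baseline_tnf,baseline_tgf baseline production rates (1/day);
#'   the defaults are the primary-case cytokine rates of [default_config()].
#' @return List of class `tam_calibration`: `tnf_production_primary`,
#'   `tnf_production_metastatic`, `tgf_production`, `tnf_fold`, `tgf_fold`.
#' @export
calibrate_cytokines <- function(panels, baseline_tnf = 2.5,
                                baseline_tgf = 1.8) {
  fold <- panel_mean(panels, "M1", "metastatic", "tnf_level") /
    panel_mean(panels, "M1", "primary", "tnf_level")
  tgf_rel <- sqrt(
    (panel_mean(panels, "M2", "primary", "tgf_level") /
       panel_mean(panels, "M2", "none", "tgf_level")) *
      (panel_mean(panels, "M2", "metastatic", "tgf_level") /
         panel_mean(panels, "M2", "none", "tgf_level")))
  out <- list(
    tnf_production_primary = baseline_tnf,
    tnf_production_metastatic = baseline_tnf * fold,
    tgf_production = baseline_tgf * tgf_rel,
    tnf_fold = fold,
    tgf_fold = tgf_rel
  )
  class(out) <- "tam_calibration"
  out
}

#' @export
print.tam_calibration <- function(x, ...) {
  cat(sprintf(paste0("cytokine calibration: TNF fold (met/prim, M1) = %.3g; ",
                     "TNF rates %.3g / %.3g; TGF rate %.3g (both types)\n"),
              x$tnf_fold, x$tnf_production_primary,
              x$tnf_production_metastatic, x$tgf_production))
  invisible(x)
}

#' Normalize transwell migration counts
#'
#' Each migrated-cell count is divided by the mean of its control group
#' (uncoated membrane, no ECM), giving relative migration.
#'
#' @param counts numeric vector of counts.
#' @param control_counts counts of the matching control group.
#' @return Numeric vector of relative migration values.
#' @export
normalize_migration <- function(counts, control_counts) {
  if (!length(control_counts)) {
    stop("control_counts must be non-empty", call. = FALSE)
  }
  m <- mean(control_counts)
  if (!is.finite(m) || m <= 0) {
    stop("control group mean must be positive", call. = FALSE)
  }
  counts / m
}

# steady-state residual of the ECM balance at density E for rates (lp, ld)
# with MDE held at M*: production lp/(1+k_p E) vs degradation ld E M*/(1+k_d E)
ecm_steady_residual <- function(E, lp, ld, m_star, k_p, k_d) {
  lp / (1 + k_p * E) - ld * E * m_star / (1 + k_d * E)
}

ecm_steady_density <- function(lp, ld, m_star, k_p, k_d, upper = 1e6) {
  stats::uniroot(ecm_steady_residual, c(0, upper), lp = lp, ld = ld,
                 m_star = m_star, k_p = k_p, k_d = k_d, tol = 1e-12)$root
}

#' Calibrate ECM production/degradation rates to a density ratio
#'
#' Chooses per-construct rate pairs `(lambda_production, lambda_degradation)`
#' so that the scalar steady state of the ECM balance (with the MDE level held
#' at its 0-D fixed point `lambda_prod_M / (lambda_prod_M + lambda_decay_M)`)
#' satisfies `E*_tECM / E*_cECM = target_density_ratio`, reflecting the
#' denser transitional matrix. The control pair is kept at the supplied
#' baseline; the transitional degradation rate is root-solved.
#'
#' @param target_density_ratio required tECM:cECM steady density ratio (> 1,
#'   or exactly 1 for the degenerate symmetric case).
#' @param lambda_production baseline production rate (both constructs).
#' @param lambda_degradation_cECM control-construct degradation rate.
#' @param k_p,k_d saturation constants.
#' @param mde_params the `mde` block used for the MDE fixed point.
#' @param tol required relative accuracy of the achieved ratio.
#' @return List of class `tam_ecm_calibration` with `cECM` and `tECM` rate
#'   pairs, the achieved `ratio`, and the steady densities.
#' @export
calibrate_ecm <- function(target_density_ratio = 1.5,
                          lambda_production = 0.3,
                          lambda_degradation_cECM = 1.5,
                          k_p = 1, k_d = 1,
                          mde_params = default_config()$mde,
                          tol = 1e-4) {
  if (target_density_ratio < 1) {
    stop("target_density_ratio must be >= 1 (transitional ECM is denser)",
         call. = FALSE)
  }
  m_star <- mde_params$lambda_production /
    (mde_params$lambda_production + mde_params$lambda_decay)
  e_c <- ecm_steady_density(lambda_production, lambda_degradation_cECM,
                            m_star, k_p, k_d)
  e_t <- target_density_ratio * e_c
  # solve for the tECM degradation rate giving steady density e_t
  f <- function(ld) ecm_steady_residual(e_t, lambda_production, ld,
                                        m_star, k_p, k_d)
  if (f(1e-9) < 0 || f(1e6) > 0) {
    stop(sprintf("calibration error: density ratio %.3g unattainable with bounded rates",
                 target_density_ratio), call. = FALSE)
  }
  ld_t <- stats::uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
  achieved <- ecm_steady_density(lambda_production, ld_t, m_star, k_p, k_d) / e_c
  if (abs(achieved - target_density_ratio) > tol * target_density_ratio) {
    stop(sprintf("calibration error: achieved ratio %.6g misses target %.6g",
                 achieved, target_density_ratio), call. = FALSE)
  }
  out <- list(
    cECM = list(lambda_production = lambda_production,
                lambda_degradation = lambda_degradation_cECM),
    tECM = list(lambda_production = lambda_production,
                lambda_degradation = ld_t),
    ratio = achieved,
    E_star_cECM = e_c,
    E_star_tECM = e_t,
    mde_fixed_point = m_star
  )
  class(out) <- "tam_ecm_calibration"
  out
}

#' @export
print.tam_ecm_calibration <- function(x, ...) {
  cat(sprintf(paste0("ECM calibration: E*(tECM)/E*(cECM) = %.4g; degradation ",
                     "rates cECM %.4g, tECM %.4g (production %.3g)\n"),
              x$ratio, x$cECM$lambda_degradation, x$tECM$lambda_degradation,
              x$cECM$lambda_production))
  invisible(x)
}
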