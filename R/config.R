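## Configuration: defaults, YAML loading, validation. The default
## configuration encodes the reference study conditions (heart rate 71
## bpm, cardiac output 5.1 L/min, mean arterial pressure 91 mmHg,
## systolic duration 41% of the cycle, coronary branch target flows
## 112/83/60 mL/min with an endo-to-epi flow ratio of 1.11, ventricular
## wall volumes 108/45/39 mL, aortic valve orifice area 4.8 cm^2).
## Myofiber material constants, vessel geometries and microvascular
## volume densities are not observable at this scale; their defaults are
## calibrated so the closed-loop model reproduces the reference
## hemodynamics (see scripts/calibrate.R and the methods vignette).

#' Default model configuration
#'
#' Returns the full nested configuration list with the reference
#' parameter set. All values are plain numbers/strings so that a config
#' round-trips through YAML unchanged.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    general = list(
      hr_bpm = 71,
      co_L_min = 5.1,
      map_mmHg = 91,
      systolic_duration_frac = 0.41,
      blood_volume_mL = 5000,
      rho_kg_m3 = 1050,
      viscosity_mPa_s = 3
    ),
    walls = list(
      density_g_ml = 1.055,
      ## segment_mass_fractions: omitted = uniform across segments
      LV = list(wall_volume_mL = 108, n_segments = 12),
      S = list(wall_volume_mL = 45, n_segments = 5),
      RV = list(wall_volume_mL = 39, n_segments = 1)
    ),
    territory_table = list( # fraction of each wall's mass per branch
      LCx = list(RV = 0.00, S = 0.00, LV = 0.42),
      LAD = list(RV = 0.00, S = 0.60, LV = 0.33),
      RCA = list(RV = 1.00, S = 0.40, LV = 0.25)
    ),
    coronary_targets = list(
      RCA = list(q0_mL_min = 112),
      LAD = list(q0_mL_min = 83),
      LCx = list(q0_mL_min = 60),
      endo_epi_ratio = 1.11
    ),
    coronary_micro = list(
      gamma = 0.06,
      layer_r = c(1 / 6, 3 / 6, 5 / 6),
      splits_main = c(0.28, 0.65, 0.07),
      splits_im = c(0.60, 0.30, 0.10),
      ## compartment blood volume densities, mL per g perfused tissue
      arteriolar_ml_per_g = 0.050,
      venular_ml_per_g = 0.025,
      epi_art_ml_per_g = 0.004,
      epi_ven_ml_per_g = 0.015,
      p0_epi_art = 85,
      p0_arteriole = 70,
      p0_venule = 22,
      p0_epi_ven = 5,
      aw_ratio_arteriole = 1.0,
      aw_ratio_venule = 1.0,
      aw_ratio_epi_art = 1.0,
      aw_ratio_epi_ven = 0.3,
      k_arteriole = 30,
      k_venule = 45,
      k_epi_art = 32,
      k_epi_ven = 10,
      compartment_length_cm = 1,
      p_ra_mean_mmHg = 4 # venous outlet pressure anchoring the reference chain
    ),
    vessels = list( # single-element non-linear tubes
      sys_art = list(length_cm = 60, A_ref_cm2 = 4.8, k = 8, p_ref_mmHg = 91, aw_ratio = 1.0, in_pericardium = FALSE),
      sys_ven = list(length_cm = 60, A_ref_cm2 = 25, k = 10, p_ref_mmHg = 4, aw_ratio = 0.3, in_pericardium = FALSE),
      pul_art = list(length_cm = 15, A_ref_cm2 = 5.0, k = 8, p_ref_mmHg = 15, aw_ratio = 1.0, in_pericardium = FALSE),
      pul_ven = list(length_cm = 15, A_ref_cm2 = 12, k = 10, p_ref_mmHg = 8, aw_ratio = 0.3, in_pericardium = FALSE),
      LM  = list(length_cm = 1.5, A_ref_cm2 = 0.160, k = 13, p_ref_mmHg = 91, aw_ratio = 1.0, in_pericardium = TRUE),
      LAD = list(length_cm = 11, A_ref_cm2 = 0.092, k = 13, p_ref_mmHg = 91, aw_ratio = 1.0, in_pericardium = TRUE),
      LCx = list(length_cm = 9, A_ref_cm2 = 0.067, k = 13, p_ref_mmHg = 91, aw_ratio = 1.0, in_pericardium = TRUE),
      RCA = list(length_cm = 12, A_ref_cm2 = 0.124, k = 13, p_ref_mmHg = 91, aw_ratio = 1.0, in_pericardium = TRUE),
      v_LAD = list(length_cm = 10, A_ref_cm2 = 0.20, k = 10, p_ref_mmHg = 5, aw_ratio = 0.3, in_pericardium = TRUE),
      v_LCx = list(length_cm = 8, A_ref_cm2 = 0.15, k = 10, p_ref_mmHg = 5, aw_ratio = 0.3, in_pericardium = TRUE),
      v_RCA = list(length_cm = 10, A_ref_cm2 = 0.25, k = 10, p_ref_mmHg = 5, aw_ratio = 0.3, in_pericardium = TRUE),
      cs_dist = list(length_cm = 3, A_ref_cm2 = 0.35, k = 10, p_ref_mmHg = 5, aw_ratio = 0.3, in_pericardium = TRUE),
      cs_prox = list(length_cm = 2, A_ref_cm2 = 0.50, k = 10, p_ref_mmHg = 4.5, aw_ratio = 0.3, in_pericardium = TRUE)
    ),
    valves = list(
      mitral = list(A_open_cm2 = 4.5, l_eff_cm = 2.0),
      aortic = list(A_open_cm2 = 4.8, l_eff_cm = 2.0),
      tricuspid = list(A_open_cm2 = 5.0, l_eff_cm = 2.0),
      pulmonary = list(A_open_cm2 = 5.0, l_eff_cm = 2.0),
      inlet_resistance_mmHg_s_ml = 0.03, # atrial venous inlets
      cs_ostium_resistance_mmHg_s_ml = 0.20
    ),
    mechanics = list(
      ventricle_mat = list(sig_act_kpa = 85, sig_pas_kpa = 0.35, k_pas = 30,
                           ls_ref = 2.0, ls0 = 1.55, v_max = 3.0,
                           strain_bounds = c(-1, 1)),
      atrium_mat = list(sig_act_kpa = 12, sig_pas_kpa = 0.6, k_pas = 14,
                        ls_ref = 2.0, ls0 = 1.51, v_max = 3,
                        strain_bounds = c(-1, 1)),
      Am_ref_cm2 = list(LV = 98, S = 49, RV = 120, LA = 65, RA = 65),
      atrial_wall_mL = list(LA = 15, RA = 12),
      activation_shape = 1.0,
      atrial_duration_s = 0.20,
      av_delay_s = 0.17, # atrial onset precedes ventricular onset by this
      pericardium = list(s_mmHg = 0.5, k = 10, vref_scale = 1.15)
    ),
    systemic = list(R_pul_mmHg_s_ml = 0.082),
    solver = list(
      dt_s = 0.001,
      scheme = "euler", # or "rk4"
      max_beats = 300,
      periodicity_tol = 1e-3,
      homeo_gain = 0.12,
      autoreg_tol = 0.01,
      autoreg_max_iter = 30,
      target_tol = 0.01
    )
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON) configuration, merges it over the defaults so a
#' partial file only needs to state deviations, and validates the result.
#'
#' @param path file path; `NULL` returns the validated defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: file not found: ", path)
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- modify_list_deep(cfg, user)
  }
  validate_config(cfg)
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Validate a configuration list
#'
#' Checks positivity, unit sanity, resistance-split normalisation, and the
#' territory-table invariants (per-wall branch fractions sum to 1). All
#' violations are collected and reported together.
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly unchanged, if valid.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)

  g <- cfg$general
  chk(g$hr_bpm > 0, "general.hr_bpm must be positive")
  chk(g$co_L_min > 0, "general.co_L_min must be positive")
  chk(g$map_mmHg > 0, "general.map_mmHg must be positive")
  chk(g$systolic_duration_frac > 0 && g$systolic_duration_frac < 1,
      "general.systolic_duration_frac must be in (0,1)")

  for (w in c("LV", "S", "RV")) {
    ws <- cfg$walls[[w]]
    chk(ws$wall_volume_mL > 0, sprintf("walls.%s.wall_volume_mL must be positive", w))
    fr <- ws$segment_mass_fractions
    if (!is.null(fr)) {
      chk(length(fr) == ws$n_segments,
          sprintf("walls.%s: segment_mass_fractions length != n_segments", w))
      chk(abs(sum(fr) - 1) < 1e-12,
          sprintf("walls.%s: segment_mass_fractions must sum to 1", w))
    }
  }

  tt <- territory_matrix(cfg)
  for (w in colnames(tt)) {
    chk(abs(sum(tt[, w]) - 1) < 1e-9,
        sprintf("territory_table: branch fractions for wall %s must sum to 1", w))
  }
  chk(all(tt >= 0 & tt <= 1), "territory_table: fractions must lie in [0,1]")

  for (nm in names(cfg$vessels)) {
    v <- cfg$vessels[[nm]]
    chk(v$length_cm > 0 && v$A_ref_cm2 > 0 && v$k > 0,
        sprintf("vessels.%s: geometry must be positive", nm))
  }
  for (nm in c("mitral", "aortic", "tricuspid", "pulmonary")) {
    chk(cfg$valves[[nm]]$A_open_cm2 > 0,
        sprintf("valves.%s.A_open_cm2 must be positive", nm))
  }
  cm <- cfg$coronary_micro
  chk(abs(sum(cm$splits_main) - 1) < 1e-9, "coronary_micro.splits_main must sum to 1")
  chk(abs(sum(cm$splits_im) - 1) < 1e-9, "coronary_micro.splits_im must sum to 1")
  chk(cm$gamma >= 0, "coronary_micro.gamma must be non-negative")
  chk(cfg$solver$dt_s > 0, "solver.dt_s must be positive")

  if (length(errs)) stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

#' Territory table as a branch x wall matrix
#'
#' @param cfg configuration list.
#' @return numeric matrix, rows LCx/LAD/RCA, columns RV/S/LV, entries the
#'   fraction of each wall's mass perfused by the branch.
#' @export
territory_matrix <- function(cfg) {
  tt <- cfg$territory_table
  branches <- names(tt)
  walls <- c("RV", "S", "LV")
  m <- matrix(0, length(branches), length(walls),
              dimnames = list(branches, walls))
  for (b in branches) for (w in walls) m[b, w] <- tt[[b]][[w]]
  m
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
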