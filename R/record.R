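## Beat record: the full time series of one simulated cardiac cycle plus
## the metadata needed to turn raw states into reported quantities.

#' Construct a beat record
#'
#' Bundles the per-step channel matrix of one cardiac cycle with the
#' vessel geometry, bed reference volumes and scenario metadata required
#' by the waveform metrics. Channels include all state variables
#' (cavity, tube and compartment volumes, valve flows), cavity/tube/
#' compartment pressures, junction and layer flows, fiber stresses and
#' the per-branch, per-layer intramyocardial pressure.
#'
#' @param M numeric matrix, one row per time step, named columns.
#' @param dt step, s.
#' @param sim simulation object the beat was produced by.
#' @return a `beat_record` list.
#' @export
beat_record <- function(M, dt, sim) {
  structure(list(
    M = M, dt = dt, n = nrow(M), period = sim$period,
    tubes = sim$tubes,
    bed_V0 = lapply(sim$beds, function(b) setNames(b$comp$V0, b$comp$name)),
    layer_q0 = lapply(sim$beds, function(b) setNames(b$layer_q0, b$layer)),
    eoa_aortic = sim$cfg$valves$aortic$A_open_cm2,
    scenario = sim$scenario,
    hr_bpm = sim$cfg$general$hr_bpm,
    beat = sim$beat
  ), class = "beat_record")
}

#' @export
print.beat_record <- function(x, ...) {
  cat(sprintf("beat_record: %s scenario, beat %d, %d steps of %.4g ms\n",
              x$scenario, x$beat, x$n, 1000 * x$dt))
  ph <- phase_segmentation(x)
  cat(sprintf("  ejection %.0f-%.0f ms; MAP %.1f mmHg, CO %.2f L/min\n",
              1000 * ph$t_open, 1000 * ph$t_ES,
              mean(x$M[, "p_sys_art"]), mean(x$M[, "q_av"]) * 0.06))
  invisible(x)
}

#' Segment a beat into systolic and diastolic windows
#'
#' The systolic window is the LV ejection interval (aortic valve open to
#' aortic valve close); diastole is everything else, including both
#' isovolumic phases (an `isovolumic_in_systole` variant brackets systole
#' from mitral closure to aortic closure instead). End-diastole is at
#' mitral valve closure, end-systole at aortic valve closure.
#'
#' @param rec a `beat_record`.
#' @param convention diastolic window convention.
#' @return list with logical index `sys`, indices `i_ED`, `i_ES`, times
#'   `t_ED`, `t_open`, `t_ES`.
#' @export
phase_segmentation <- function(rec, convention = c("ejection",
                                                   "isovolumic_in_systole")) {
  convention <- match.arg(convention)
  q_av <- rec$M[, "q_av"]
  q_mv <- rec$M[, "q_mv"]
  eject <- q_av > 1e-9
  if (!any(eject)) stop("phase_segmentation: no ejection in this beat")
  i_open <- which(eject)[1]
  i_ES <- max(which(eject))
  closed_before <- which(q_mv[seq_len(i_open)] > 1e-9)
  i_ED <- if (length(closed_before)) max(closed_before) else 1L
  sys <- logical(rec$n)
  if (convention == "ejection") sys[i_open:i_ES] <- TRUE else sys[i_ED:i_ES] <- TRUE
  list(sys = sys, i_ED = i_ED, i_ES = i_ES, i_open = i_open,
       t_ED = (i_ED - 1) * rec$dt, t_open = (i_open - 1) * rec$dt,
       t_ES = (i_ES - 1) * rec$dt)
}

#' Inlet flow velocity of a conduit vessel
#'
#' Velocity is flow divided by the instantaneous lumen area of the vessel
#' (stressed volume over length), in m/s.
#'
#' @param rec a `beat_record`.
#' @param vessel vessel name (e.g. "LAD").
#' @return numeric vector, m/s, one value per time step.
#' @export
vessel_velocity <- function(rec, vessel) {
  flows <- c(LM = "q_ao_lm", LAD = "q_lm_lad", LCx = "q_lm_lcx",
             RCA = "q_ao_rca", cs_dist = "q_csd_csp", cs_prox = "q_csp_ra",
             v_LAD = "q_vlad_csd", v_LCx = "q_vlcx_csd", v_RCA = "q_vrca_csp")
  if (!vessel %in% names(flows)) stop("vessel_velocity: no inlet flow for ", vessel)
  tb <- rec$tubes[rec$tubes$name == vessel, ]
  A <- (rec$M[, paste0("V_", vessel)] - tb$Vu) / tb$L
  flow_velocity(rec$M[, flows[[vessel]]], A)
}
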