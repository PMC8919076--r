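## Waveform metrics reported by the model: peak diastolic-to-systolic
## velocity ratio, diastolic velocity-time-integral fraction, transmural
## diameter changes, mean flows and transvalvular gradients.

#' Peak diastolic-to-systolic flow velocity ratio
#'
#' Ratio of the peak velocity outside the LV ejection window to the peak
#' velocity inside it.
#'
#' @param v velocity series over one beat (any unit).
#' @param phases output of [phase_segmentation()].
#' @return the ratio; `NA` with a warning when the systolic peak is not
#'   positive.
#' @export
pdsvr <- function(v, phases) {
  ps <- max(v[phases$sys])
  pd <- max(v[!phases$sys])
  if (ps <= 0) {
    warning("pdsvr: non-positive systolic peak; ratio undefined")
    return(NA_real_)
  }
  pd / ps
}

#' Diastolic-to-total velocity time integral
#'
#' Fraction of the antegrade (positive-clipped) velocity-time integral
#' accumulated outside the ejection window. Retrograde flow is excluded
#' from both integrals, mirroring Doppler envelope tracing.
#'
#' @inheritParams pdsvr
#' @return fraction in [0, 1]; `NA` with a warning for a zero total
#'   integral.
#' @export
dtvi <- function(v, phases) {
  vp <- pmax(v, 0)
  tot <- sum(vp)
  if (tot <= 0) {
    warning("dtvi: zero antegrade integral; fraction undefined")
    return(NA_real_)
  }
  sum(vp[!phases$sys]) / tot
}

#' End-diastole to end-systole diameter change
#'
#' Diameter is derived from compartment volume assuming a circular
#' cross-section and constant length (`d` proportional to `sqrt(V)`);
#' the change is reported in percent of the end-diastolic diameter,
#' negative for systolic compression.
#'
#' @param V volume series over one beat, mL.
#' @param phases output of [phase_segmentation()].
#' @return percent change `100*(d_ES - d_ED)/d_ED`.
#' @export
diameter_change_ed_es <- function(V, phases) {
  d_ed <- sqrt(V[phases$i_ED])
  d_es <- sqrt(V[phases$i_ES])
  100 * (d_es - d_ed) / d_ed
}

#' Retrograde flow fraction of a velocity series
#'
#' Companion to the clipped integral convention of [dtvi()]: the fraction
#' of total absolute velocity-time integral carried by retrograde flow.
#'
#' @param v velocity series.
#' @return fraction in [0, 1].
#' @export
retrograde_fraction <- function(v) {
  tot <- sum(abs(v))
  if (tot == 0) return(0)
  sum(pmax(-v, 0)) / tot
}

#' Beat-averaged branch flow
#'
#' @param rec a `beat_record`.
#' @param branch "LAD", "LCx" or "RCA".
#' @return mean inlet flow, mL/min.
#' @export
mean_branch_flow <- function(rec, branch) {
  mls_to_mlmin(mean(rec$M[, paste0("q_in_", branch)]))
}

#' Beat-averaged subendo-to-subepi flow ratio of a bed
#'
#' @inheritParams mean_branch_flow
#' @return dimensionless ratio of mean arteriolar layer flows.
#' @export
endo_epi_ratio <- function(rec, branch) {
  mean(rec$M[, paste0("q1_", branch, "_subendo")]) /
    mean(rec$M[, paste0("q1_", branch, "_subepi")])
}

#' Mean transvalvular aortic gradient
#'
#' Time-average of the LV-to-aorta pressure difference during forward
#' (ejection) flow.
#'
#' @param rec a `beat_record`.
#' @return mmHg.
#' @export
mean_aortic_gradient <- function(rec) {
  fwd <- rec$M[, "q_av"] > 1e-9
  mean(rec$M[fwd, "dp_av"])
}

#' Peak transvalvular aortic jet velocity
#'
#' Jet velocity from valve flow and effective orifice area.
#'
#' @param rec a `beat_record`.
#' @return m/s.
#' @export
peak_aortic_velocity <- function(rec) {
  max(flow_velocity(rec$M[, "q_av"], rec$eoa_aortic))
}

#' Summary metrics table of a converged beat
#'
#' Collates the reported metrics: global hemodynamics (CO, MAP, peak LV
#' pressure, mean transvalvular gradient, peak aortic jet velocity), mean
#' branch and coronary sinus flows, endo-to-epi flow ratios, coronary
#' velocity waveform indices (pDSVR, DTVi, peak systolic velocity) per
#' artery, and end-diastole to end-systole diameter changes of the
#' subendocardial arterioles.
#'
#' @param rec a `beat_record`.
#' @return data.frame with columns `site`, `metric`, `value`, `units`.
#' @export
summary_table <- function(rec) {
  ph <- phase_segmentation(rec)
  row <- function(site, metric, value, units)
    data.frame(site = site, metric = metric, value = value, units = units)
  out <- rbind(
    row("global", "cardiac_output", mean(rec$M[, "q_av"]) * 0.06, "L/min"),
    row("global", "mean_arterial_pressure", mean(rec$M[, "p_sys_art"]), "mmHg"),
    row("global", "peak_lv_pressure", max(rec$M[, "p_lv"]), "mmHg"),
    row("global", "mean_aortic_gradient", mean_aortic_gradient(rec), "mmHg"),
    row("global", "peak_aortic_velocity", peak_aortic_velocity(rec), "m/s"),
    row("cs_dist", "mean_flow", mls_to_mlmin(mean(rec$M[, "q_csd_csp"])), "mL/min")
  )
  for (b in BED_ORDER) {
    v <- vessel_velocity(rec, b)
    out <- rbind(
      out,
      row(b, "mean_flow", mean_branch_flow(rec, b), "mL/min"),
      row(b, "endo_epi_ratio", endo_epi_ratio(rec, b), "-"),
      row(b, "pdsvr", pdsvr(v, ph), "-"),
      row(b, "dtvi", dtvi(v, ph), "-"),
      row(b, "peak_systolic_velocity", max(v[ph$sys]), "m/s"),
      row(b, "diameter_change_subendo_arteriolar",
          diameter_change_ed_es(rec$M[, paste0("V_", b, "_a_subendo")], ph), "%")
    )
  }
  v_lm <- vessel_velocity(rec, "LM")
  out <- rbind(out,
               row("LM", "pdsvr", pdsvr(v_lm, ph), "-"),
               row("LM", "dtvi", dtvi(v_lm, ph), "-"))
  rownames(out) <- NULL
  out
}

#' Write metrics and beat time series to CSV
#'
#' `metrics.csv` is long-format (`scenario, site, metric, value, units`);
#' `beat.csv` is long-format (`t, channel, value`). A `metrics.json`
#' mirror of the metrics is written alongside.
#'
#' @param rec a `beat_record`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_outputs <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- summary_table(rec)
  met <- cbind(scenario = rec$scenario, met)
  p1 <- file.path(dir, "metrics.csv")
  utils::write.csv(met, p1, row.names = FALSE)
  tall <- data.frame(
    t = rep(rec$M[, "t"], ncol(rec$M) - 1),
    channel = rep(colnames(rec$M)[-1], each = nrow(rec$M)),
    value = as.vector(rec$M[, -1])
  )
  p2 <- file.path(dir, "beat.csv")
  utils::write.csv(tall, p2, row.names = FALSE)
  p3 <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    setNames(as.list(met$value), paste(met$scenario, met$site, met$metric, sep = ".")),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
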