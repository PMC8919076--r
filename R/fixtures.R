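## Analytic fixture waveforms and a standalone driven coronary bed rig.
## These let the microcirculation and coupling modules be exercised and
## tested in isolation from the full closed-loop heart.

#' Analytic half-sinusoid pressure/stress waveforms
#'
#' Periodic half-sinusoid with configurable peak and systolic fraction,
#' sampled at the solver step: `peak * sin(pi * t/T_sys)` during systole,
#' `baseline` otherwise. Used as a stand-in LV pressure, and (scaled) as
#' a matched fiber-stress time course.
#'
#' @param peak peak value (e.g. mmHg).
#' @param hr_bpm heart rate, bpm.
#' @param systolic_frac systolic fraction of the cycle.
#' @param dt sample step, s.
#' @param baseline diastolic value.
#' @return list with `t`, `y`, `period`, `dt`.
#' @export
fixture_waveform <- function(peak, hr_bpm = 71, systolic_frac = 0.41,
                             dt = 0.001, baseline = 0) {
  period <- 60 / hr_bpm
  n <- round(period / dt)
  t <- (seq_len(n) - 1) * (period / n)
  x <- t / (systolic_frac * period)
  y <- ifelse(x < 1, baseline + (peak - baseline) * sin(pi * x), baseline)
  list(t = t, y = y, period = period, dt = period / n)
}

#' Standalone driven coronary bed rig
#'
#' A single coronary bed with constant arterial and venous boundary
#' pressures and prescribed analytic intramyocardial pressure waveforms
#' per layer: CEP from a half-sinusoid cavity pressure (pericardial
#' pressure zero) and VE from a matched fiber-stress waveform whose peak
#' gives VE = 20% of the peak cavity pressure.
#'
#' @param peak_lv_pressure peak of the driving cavity pressure, mmHg.
#' @param hr_bpm heart rate, bpm.
#' @param systolic_frac systolic fraction of the cycle.
#' @param q0_mlmin bed target flow, mL/min.
#' @param mass_g perfused mass, g.
#' @param p_art,p_ven constant boundary pressures, mmHg.
#' @param gamma VE scaling applied to the fiber-stress waveform.
#' @param sigma_peak peak of the matched fiber-stress waveform, mmHg; the
#'   default is sized so that VE peaks at 20% of the peak cavity pressure
#'   when `gamma = 0.06`, and is held fixed as `gamma` varies (so a gamma
#'   sweep isolates the stiffness mechanism).
#' @param micro microcirculation parameter list.
#' @param p0_mode compartment pressure anchoring, see [build_bed()].
#' @param Z_in,Z_out boundary wave impedances, mmHg*s/mL.
#' @param dt integration step, s.
#' @return a `bed_fixture` list with the bed, boundary conditions and the
#'   per-layer IMP waveform matrix.
#' @export
make_driven_bed_fixture <- function(peak_lv_pressure, hr_bpm = 71,
                                    systolic_frac = 0.41,
                                    q0_mlmin = 83, mass_g = 65.8,
                                    p_art = 91, p_ven = 5, gamma = 0.06,
                                    sigma_peak = 0.20 * peak_lv_pressure / 0.06,
                                    micro = default_config()$coronary_micro,
                                    p0_mode = "operating",
                                    Z_in = 3, Z_out = 1,
                                    dt = 0.001) {
  stopifnot(hr_bpm > 0, systolic_frac > 0, peak_lv_pressure >= 0)
  bed <- build_bed("LAD", mass_g, q0_mlmin, p_art, p_ven, 1.11, micro, p0_mode)
  wf <- fixture_waveform(peak_lv_pressure, hr_bpm, systolic_frac, dt)
  sig <- fixture_waveform(sigma_peak, hr_bpm, systolic_frac, dt)$y
  r <- micro$layer_r
  imp <- sapply(seq_along(r), function(j) cep(r[j], wf$y, 0) + ve(sig, gamma))
  colnames(imp) <- c("subepi", "mid", "subendo")
  structure(list(bed = bed, p_art = p_art, p_ven = p_ven,
                 Z_in = Z_in, Z_out = Z_out, imp = imp, p_lv = wf$y,
                 t = wf$t, dt = wf$dt, period = wf$period), class = "bed_fixture")
}

#' Integrate a driven bed fixture to a periodic state
#'
#' Explicit Euler at the fixture step, repeated over `n_beats` cycles;
#' returns the last cycle's compartment volumes and layer flows.
#'
#' @param rig a `bed_fixture`.
#' @param n_beats number of cycles to integrate.
#' @return list with matrices `V` (steps x 8 compartments), `q1`, `qm`,
#'   `q2` (steps x 3 layers), vectors `q_in`, `q_out`, and the final
#'   state.
#' @export
run_bed_fixture <- function(rig, n_beats = 10) {
  bed <- rig$bed
  V <- bed$comp$V0
  n <- length(rig$t)
  Vrec <- matrix(0, n, 8, dimnames = list(NULL, bed$comp$name))
  q1 <- qm <- q2 <- matrix(0, n, 3, dimnames = list(NULL, colnames(rig$imp)))
  q_in <- q_out <- numeric(n)
  for (b in seq_len(n_beats)) {
    last <- b == n_beats
    for (i in seq_len(n)) {
      md <- micro_derivatives(bed, V, rig$p_art, rig$Z_in, rig$p_ven,
                              rig$Z_out, rig$imp[i, ], p_peri = 0)
      if (last) {
        Vrec[i, ] <- V
        q1[i, ] <- md$q1; qm[i, ] <- md$qm; q2[i, ] <- md$q2
        q_in[i] <- md$q_in; q_out[i] <- md$q_out
      }
      V <- V + rig$dt * md$dV
    }
  }
  list(V = Vrec, q1 = q1, qm = qm, q2 = q2, q_in = q_in, q_out = q_out,
       state = V, dt = rig$dt)
}
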