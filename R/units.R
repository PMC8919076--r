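## Internal unit system: pressure mmHg, volume mL, time s, length cm, area cm2.
## Derived: flow mL/s, resistance mmHg*s/mL, compliance mL/mmHg,
## inertance mmHg*s^2/mL. Velocities are reported in m/s at the API boundary.

#' Unit conversion helpers
#'
#' The package computes in classic hemodynamic units (mmHg, mL, s, cm).
#' These helpers convert at module boundaries: myofiber stress is configured
#' in kPa, velocities are reported in m/s, flows in mL/min where the
#' clinical literature uses them.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
kpa_to_mmhg <- function(x) x * 7.50061683

#' @rdname units
#' @export
mmhg_to_kpa <- function(x) x / 7.50061683

#' @rdname units
#' @export
mls_to_lmin <- function(x) x * 60 / 1000

#' @rdname units
#' @export
mls_to_mlmin <- function(x) x * 60

## 1 mmHg = 133.322 Pa
.PA_PER_MMHG <- 133.322387415

#' Blood velocity from flow and lumen area
#'
#' @param q flow, mL/s.
#' @param A cross-sectional area, cm^2.
#' @return velocity in m/s (flow / area, converted).
#' @export
flow_velocity <- function(q, A) (q / A) / 100

## Bernoulli orifice pressure drop, mmHg, for flow q (mL/s) through an
## effective orifice A_eff (cm^2) with proximal area A_prox (cm^2).
## dp = rho/2 * (v_eff^2 - v_prox^2), signed with the flow direction.
bernoulli_drop <- function(q, A_eff, A_prox, rho = 1050) {
  coef <- (rho / 2) / .PA_PER_MMHG * 1e-4 # mmHg per (mL/s / cm^2)^2
  coef * q * abs(q) * (1 / A_eff^2 - 1 / A_prox^2)
}

## Blood inertance of an orifice/short tube, mmHg*s^2/mL.
## L = rho * l / A with l in cm, A in cm^2.
orifice_inertance <- function(l_cm, A_cm2, rho = 1050) {
  rho * (l_cm / 100) / (A_cm2 * 1e-4) / .PA_PER_MMHG * 1e-6
}
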