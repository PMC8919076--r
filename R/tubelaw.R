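## Collapsible-tube pressure-area law shared by conduit vessels and the
## lumped microcirculatory compartments, plus wave speed / impedance.

#' Transmural pressure of a vessel from its lumen area
#'
#' Non-linear power-law relation between transmural pressure and lumen
#' cross-sectional area, with a collapse penalty active at small areas so
#' that transmural pressure becomes progressively negative as the lumen
#' approaches collapse:
#'
#' \deqn{p_{trans} = p_0\left[\left(\frac{A + 0.5 A_w}{A_0 + 0.5 A_w}\right)^{k/3-1}
#'   - \max\!\left(0,\ (A/A_0)^{-0.7} (A_w/A_0)^{0.4} - 1\right)^2\right]}
#'
#' At the reference area \eqn{A = A_0} (with wall area \eqn{A_w \le A_0}) the
#' collapse term is inactive and \eqn{p_{trans} = p_0}. The exponent is
#' \eqn{k/3 - 1} (not \eqn{k/3} then minus one): only this convention anchors
#' the reference state.
#'
#' @param A lumen area, cm^2 (or any unit consistent with `A0`, `Aw`).
#' @param p0 reference transmural pressure, mmHg.
#' @param A0 reference lumen area.
#' @param Aw vessel wall cross-sectional area.
#' @param k wall stiffness exponent (dimensionless); larger is stiffer.
#' @return transmural pressure, mmHg.
#' @export
tube_law_pressure <- function(A, p0, A0, Aw, k) {
  if (any(A <= 0)) stop("tube_law_pressure: lumen area must be positive")
  distension <- ((A + 0.5 * Aw) / (A0 + 0.5 * Aw))^(k / 3 - 1)
  g <- (A / A0)^(-0.7) * (Aw / A0)^(0.4) - 1
  p0 * (distension - pmax(0, g)^2)
}

#' Analytic slope dp/dA of the tube law
#'
#' @inheritParams tube_law_pressure
#' @return derivative of transmural pressure with respect to area,
#'   mmHg/cm^2.
#' @export
tube_law_dpda <- function(A, p0, A0, Aw, k) {
  if (any(A <= 0)) stop("tube_law_dpda: lumen area must be positive")
  e1 <- k / 3 - 1
  d_dist <- e1 * ((A + 0.5 * Aw) / (A0 + 0.5 * Aw))^(e1 - 1) / (A0 + 0.5 * Aw)
  g <- (A / A0)^(-0.7) * (Aw / A0)^(0.4) - 1
  dg <- -0.7 * (A / A0)^(-1.7) * (Aw / A0)^(0.4) / A0
  d_col <- (g > 0) * 2 * g * dg
  p0 * (d_dist - d_col)
}

#' Pulse wave speed of a compliant tube
#'
#' Linearised (Moens-Korteweg type) wave speed
#' \eqn{c = \sqrt{(A/\rho)\, dp/dA}} evaluated from the implemented tube
#' law. A small positive floor is applied to the slope so that wave speed
#' stays defined through the collapse regime.
#'
#' @inheritParams tube_law_pressure
#' @param rho blood density, kg/m^3.
#' @return wave speed, m/s.
#' @export
wave_speed <- function(A, p0, A0, Aw, k, rho = 1050) {
  dpda <- tube_law_dpda(A, p0, A0, Aw, k)
  ## mmHg/cm^2 -> Pa/m^2 is *1.33322e6; A cm^2 -> m^2 is *1e-4
  c2 <- (A * 1e-4) * pmax(dpda, 0.05 * abs(p0) / A0) * (.PA_PER_MMHG * 1e4) / rho
  sqrt(c2)
}

#' Characteristic wave impedance of a tube end
#'
#' \eqn{Z = \rho c / A}, pressure-dependent through both the local wave
#' speed and the local area.
#'
#' @inheritParams wave_speed
#' @return impedance, mmHg*s/mL.
#' @export
wave_impedance <- function(A, p0, A0, Aw, k, rho = 1050) {
  cc <- wave_speed(A, p0, A0, Aw, k, rho)
  rho * cc / (A * 1e-4) / .PA_PER_MMHG * 1e-6
}

#' Reflection coefficient at a two-tube junction
#'
#' For a wave travelling from a tube with source impedance `Z_up` into a
#' termination of impedance `Z_down`:
#' \eqn{\Gamma = (Z_{down} - Z_{up}) / (Z_{down} + Z_{up})}.
#' Matched impedances give 0; a closed end (`Z_down = Inf`) gives +1.
#'
#' @param Z_up,Z_down impedances, mmHg*s/mL.
#' @return dimensionless reflection coefficient.
#' @export
junction_reflection <- function(Z_up, Z_down) {
  ifelse(is.infinite(Z_down), 1, (Z_down - Z_up) / (Z_down + Z_up))
}
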