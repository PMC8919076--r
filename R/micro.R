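## Lumped coronary microcirculation: one epicardial arterial compartment,
## three transmural layers (subepi, mid, subendo) each with an arteriolar
## and a venular compartment, and one epicardial venous compartment.

#' Volume-dependent Poiseuille resistance
#'
#' Each compartment's resistance scales with the inverse square of its
#' instantaneous volume, \eqn{R = R_0 V_0^2 / V^2}: halving the volume
#' quadruples the resistance. Volumes are smoothly floored at 1% of the
#' reference volume so the resistance stays finite in the collapse regime.
#'
#' @param V instantaneous volume, mL.
#' @param R0 reference resistance at `V = V0`, mmHg*s/mL.
#' @param V0 reference volume, mL.
#' @return resistance, mmHg*s/mL.
#' @export
poiseuille_resistance <- function(V, R0, V0) {
  Veff <- soft_floor(V, V0)
  R0 * V0^2 / Veff^2
}

## Smooth volume floor at 1% of V0: exactly V away from the floor,
## smoothly clamped (softplus) to 0.01*V0 as V -> 0.
soft_floor <- function(V, V0) {
  floor <- rep_len(0.01 * V0, length(V))
  w <- rep_len(0.02 * V0, length(V))
  z <- (V - floor) / w
  low <- which(z <= 30)
  if (length(low)) V[low] <- floor[low] + w[low] * log1p(exp(z[low]))
  V
}

#' Reference resistance network of one coronary bed
#'
#' Total bed resistance follows from the mean perfusion pressure drop and
#' the branch target flow, \eqn{R_0 = \Delta p_0 / q_0}. It is split
#' 28% : 65% : 7% over the epicardial arterial, intramyocardial, and
#' epicardial venous compartments; the intramyocardial block is split
#' 60% : 30% : 10% over arteriolar, middle, and venular resistances.
#' Layer target flows honour the subendo-to-subepi flow ratio, with the
#' mid layer halfway between.
#'
#' @param q0_mlmin branch target flow, mL/min.
#' @param p_art mean arterial (perfusion inlet) pressure, mmHg.
#' @param p_ven mean venous (outlet) pressure, mmHg.
#' @param endo_epi target subendocardial-to-subepicardial flow ratio.
#' @param splits_main fractions (epicardial arterial, intramyocardial,
#'   epicardial venous); must sum to 1.
#' @param splits_im fractions (arteriolar R1, middle Rm, venular R2);
#'   must sum to 1.
#' @return list with `R_total`, `R_a`, `R_v` (mmHg*s/mL), layer table
#'   `layers` (one row per layer with target flow `q0` in mL/s and
#'   resistances `R1`, `Rm`, `R2`), and the layer flow fractions.
#' @export
reference_resistances <- function(q0_mlmin, p_art, p_ven,
                                  endo_epi = 1.11,
                                  splits_main = c(0.28, 0.65, 0.07),
                                  splits_im = c(0.60, 0.30, 0.10)) {
  stopifnot(q0_mlmin > 0)
  if (abs(sum(splits_main) - 1) > 1e-9 || abs(sum(splits_im) - 1) > 1e-9)
    stop("reference_resistances: resistance splits must each sum to 1")
  dp <- p_art - p_ven
  if (dp <= 0) stop("reference_resistances: non-positive perfusion pressure")
  q0 <- q0_mlmin / 60 # mL/s
  R_total <- dp / q0
  frac <- c(subepi = 1, mid = (1 + endo_epi) / 2, subendo = endo_epi)
  frac <- frac / sum(frac)
  q0_l <- q0 * frac
  ## parallel layer resistances recombine to the bed intramyocardial block
  R_im_l <- splits_main[2] * R_total * q0 / q0_l
  layers <- data.frame(
    layer = names(frac),
    frac = as.numeric(frac),
    q0 = as.numeric(q0_l),
    R1 = as.numeric(splits_im[1] * R_im_l),
    Rm = as.numeric(splits_im[2] * R_im_l),
    R2 = as.numeric(splits_im[3] * R_im_l),
    row.names = NULL
  )
  list(R_total = R_total,
       R_a = splits_main[1] * R_total,
       R_v = splits_main[3] * R_total,
       layers = layers)
}

#' Instantaneous state derivatives of one coronary bed
#'
#' Implements the arterial-venous circuit: a pressure-difference-controlled
#' flow source across the arterial wave impedance feeds the epicardial
#' arterial compartment, which drains through the (shared, flow-apportioned)
#' epicardial arterial resistance and each layer's arteriolar resistance
#' into the arteriolar compartments; layer flow continues through the shared
#' middle resistance to the venular compartments and through the venular and
#' epicardial venous resistances to the epicardial venous compartment, which
#' empties across the venous wave impedance. Intramyocardial pressure acts
#' as external pressure on the six intramyocardial compartments; pericardial
#' pressure acts on the two epicardial compartments.
#'
#' @param bed coronary bed parameter object (see `build_bed`).
#' @param V named numeric vector of the 8 compartment volumes, order
#'   `ea, a1, a2, a3, v1, v2, v3, ev` (layers subepi, mid, subendo).
#' @param p_in pressure at the feeding artery tube end, mmHg.
#' @param Z_in source impedance of the feeding artery end, mmHg*s/mL.
#' @param p_out pressure at the draining vein tube end, mmHg.
#' @param Z_out impedance of the draining vein end, mmHg*s/mL.
#' @param p_im intramyocardial pressure per layer (subepi, mid, subendo), mmHg.
#' @param p_peri pericardial pressure acting on the epicardial compartments,
#'   mmHg.
#' @return list with `dV` (8 volume derivatives, mL/s), inlet/outlet flows
#'   `q_in`, `q_out`, layer flows `q1` (arteriolar, crossing R1), `qm`,
#'   `q2` (venular, crossing R2), and compartment pressures `p`.
#' @export
micro_derivatives <- function(bed, V, p_in, Z_in, p_out, Z_out, p_im, p_peri) {
  pv <- bed$par # flat parameter vectors, compartment order
  Veff <- soft_floor(V, pv$V0)
  A <- Veff / pv$L
  ptr <- tube_law_pressure(A, pv$p0, pv$A0, pv$Aw, pv$k)
  pext <- c(p_peri, p_im, p_im, p_peri)
  p <- ptr + pext

  i_ea <- 1L; i_a <- 2:4; i_v <- 5:7; i_ev <- 8L
  ## wave impedances of the epicardial compartments (pressure-dependent)
  Zav <- wave_impedance(A[c(i_ea, i_ev)], pv$p0[c(1, 8)], pv$A0[c(1, 8)],
                        pv$Aw[c(1, 8)], pv$k[c(1, 8)])
  Za <- Zav[1]; Zv <- Zav[2]

  Ra <- poiseuille_resistance(V[i_ea], bed$R_a0, pv$V0[1])
  Rv <- poiseuille_resistance(V[i_ev], bed$R_v0, pv$V0[8])
  R1 <- poiseuille_resistance(V[i_a], bed$R10, pv$V0[i_a])
  R2 <- poiseuille_resistance(V[i_v], bed$R20, pv$V0[i_v])
  ## Rm represents the capillaries, whose volume is not a model state;
  ## it therefore keeps its reference value.
  Rm <- bed$Rm0

  w <- bed$w_layer # apportionment of shared epicardial resistances
  q_in <- (p_in - p[i_ea]) / (Z_in + Za)
  q1 <- (p[i_ea] - p[i_a]) / (Ra * w + R1)
  qm <- (p[i_a] - p[i_v]) / Rm
  q2 <- (p[i_v] - p[i_ev]) / (R2 + Rv * w)
  q_out <- (p[i_ev] - p_out) / (Zv + Z_out)

  dV <- numeric(8)
  dV[i_ea] <- q_in - sum(q1)
  dV[i_a] <- q1 - qm
  dV[i_v] <- qm - q2
  dV[i_ev] <- sum(q2) - q_out
  list(dV = dV, q_in = q_in, q_out = q_out, q1 = q1, qm = qm, q2 = q2,
       p = p, Za = Za, Zv = Zv)
}

#' Construct a coronary bed parameter object
#'
#' Sizes compartment reference volumes from the perfused territory mass
#' and derives the resistance network from the target flow (see
#' [reference_resistances()]). Compartment reference pressures `p0` come
#' in two flavours: `"operating"` (default) uses the configured typical
#' operating pressures (by default arteriolar 70, venular 22, epicardial
#' arterial 85, epicardial venous 5 mmHg), so compartments sit near `V0` (hence
#' near `R0`) at their in-vivo working pressures and the autoregulation
#' tuning absorbs the residual mismatch in the arteriolar reference
#' resistance; `"chain"` anchors `p0` to the node pressures of the ideal
#' reference resistor chain, making `V = V0` at zero intramyocardial
#' pressure an exact steady state with layer flows at target (used by the
#' isolated-bed consistency checks).
#'
#' @param branch branch label ("LAD", "LCx" or "RCA").
#' @param mass_g perfused territory mass, g.
#' @param q0_mlmin branch target flow, mL/min.
#' @param p_art,p_ven mean perfusion inlet / outlet pressures, mmHg.
#' @param endo_epi target subendo-to-subepi flow ratio.
#' @param micro microcirculation parameter list (volumes per gram, wall
#'   area ratios, stiffness exponents, resistance splits, reference
#'   pressures); see `default_config()$coronary_micro`.
#' @param p0_mode `"operating"` or `"chain"` (see Details).
#' @return a `coro_bed` list.
#' @export
build_bed <- function(branch, mass_g, q0_mlmin, p_art, p_ven,
                      endo_epi = 1.11, micro = default_config()$coronary_micro,
                      p0_mode = c("operating", "chain")) {
  p0_mode <- match.arg(p0_mode)
  rr <- reference_resistances(q0_mlmin, p_art, p_ven, endo_epi,
                              micro$splits_main, micro$splits_im)
  lay <- rr$layers
  if (p0_mode == "chain") {
    ## node pressures of the reference chain (identical across layers by
    ## construction of the layer resistances)
    dp <- p_art - p_ven
    sm <- micro$splits_main; si <- micro$splits_im
    p_ea0 <- p_art
    p_a0 <- p_art - (sm[1] + sm[2] * si[1]) * dp
    p_v0 <- p_art - (sm[1] + sm[2] * (si[1] + si[2])) * dp
    ## the venular resistance R_v sits upstream of the epicardial venous
    ## compartment, which therefore rests at the outlet pressure
    p_ev0 <- p_ven
  } else {
    p_ea0 <- micro$p0_epi_art
    p_a0 <- micro$p0_arteriole
    p_v0 <- micro$p0_venule
    p_ev0 <- micro$p0_epi_ven
  }

  m_layer <- mass_g / 3 # equal-thickness transmural layers
  V0_a <- micro$arteriolar_ml_per_g * m_layer
  V0_v <- micro$venular_ml_per_g * m_layer
  V0_ea <- micro$epi_art_ml_per_g * mass_g
  V0_ev <- micro$epi_ven_ml_per_g * mass_g

  L <- micro$compartment_length_cm
  V0 <- c(V0_ea, rep(V0_a, 3), rep(V0_v, 3), V0_ev)
  comp <- data.frame(
    name = c("ea", paste0("a", 1:3), paste0("v", 1:3), "ev"),
    V0 = V0,
    L = L,
    A0 = V0 / L,
    Aw = V0 / L * c(micro$aw_ratio_epi_art, rep(micro$aw_ratio_arteriole, 3),
                    rep(micro$aw_ratio_venule, 3), micro$aw_ratio_epi_ven),
    k = c(micro$k_epi_art, rep(micro$k_arteriole, 3),
          rep(micro$k_venule, 3), micro$k_epi_ven),
    p0 = c(p_ea0, rep(p_a0, 3), rep(p_v0, 3), p_ev0)
  )
  structure(list(
    branch = branch, mass_g = mass_g,
    q0 = q0_mlmin / 60, layer_q0 = lay$q0, layer = lay$layer,
    comp = comp,
    par = list(V0 = comp$V0, L = comp$L, A0 = comp$A0, Aw = comp$Aw,
               k = comp$k, p0 = comp$p0),
    R_a0 = rr$R_a, R_v0 = rr$R_v,
    R10 = lay$R1, Rm0 = lay$Rm, R20 = lay$R2,
    w_layer = bed_weights(lay$q0),
    endo_epi = endo_epi
  ), class = "coro_bed")
}

## apportionment weights of a shared resistance over parallel layers:
## layer l carries q0_l of q0, so its share is R * q0/q0_l and the
## parallel combination recovers R.
bed_weights <- function(q0_l) sum(q0_l) / q0_l

#' Compartment diameter from volume
#'
#' Assuming a circular cross-section and constant length, diameter scales
#' with the square root of volume; diameters are reported normalized, so
#' the nominal length cancels.
#'
#' @param V volume, mL.
#' @param V_ref normalizing volume (e.g. end-diastolic), mL.
#' @param d_ref diameter at `V_ref` (default 1 for normalized output).
#' @return diameter in units of `d_ref`.
#' @export
compartment_diameter <- function(V, V_ref, d_ref = 1) d_ref * sqrt(V / V_ref)
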