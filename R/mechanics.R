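## One-fiber myofiber mechanics, spherical-cap wall geometry, three-wall
## (TriSeg) ventricular force equilibrium, and the pericardial constraint.
##
## A wall is a thick spherical cap characterised by midwall area Am,
## midwall curvature Cm and (fixed) wall volume Vw. Myofiber tension is
## assumed homogeneous over the wall; representative midwall fiber strain
## follows from the area ratio with a thickness correction, and wall
## tension follows from fiber stress via the thick-wall factor g(z).

#' Activation time course of a cardiac wall
#'
#' Smooth periodic twitch: `sin(pi*x)^shape` on the active interval
#' `x = (t - onset)/duration` in (0, 1), zero elsewhere. The ventricular
#' duration is the configured systolic fraction of the cycle.
#'
#' @param t time, s (scalar or vector).
#' @param period cardiac cycle length, s.
#' @param duration active twitch duration, s.
#' @param onset activation onset within the cycle, s.
#' @param shape exponent controlling twitch skew/width.
#' @return activation level in [0, 1].
#' @export
activation <- function(t, period, duration, onset = 0, shape = 1.5) {
  x <- ((t - onset) %% period) / duration
  ifelse(x > 0 & x < 1, sin(pi * x)^shape, 0)
}

#' Total myofiber stress of a wall segment
#'
#' Sum of an active, length- and activation-dependent component and a
#' passive exponential component:
#' active = `sig_act * act * (Ls - ls0)/(ls_ref - ls0)` (zero below slack
#' length), passive = `sig_pas * (exp(k_pas * eps) - 1)` for positive
#' natural strain `eps`, zero in compression. Sarcomere length is
#' `Ls = ls_ref * exp(eps)`.
#'
#' @param strain natural myofiber strain (0 at the zero-stress reference).
#' @param act activation level in [0, 1].
#' @param mat material parameter list: `sig_act_kpa`, `sig_pas_kpa`,
#'   `k_pas`, `ls_ref` (um), `ls0` (um), `strain_bounds`.
#' @param segment id used in error messages.
#' @return total fiber stress, kPa.
#' @export
segment_stress <- function(strain, act, mat, segment = "wall") {
  b <- mat$strain_bounds
  if (any(strain < b[1] | strain > b[2]))
    stop(sprintf("segment_stress: strain out of physiologic bounds in %s", segment))
  if (any(act < 0 | act > 1)) stop("segment_stress: activation outside [0, 1]")
  comp <- segment_stress_components(strain, act, mat)
  comp$active + comp$passive
}

segment_stress_components <- function(strain, act, mat) {
  ls <- mat$ls_ref * exp(strain)
  f_len <- pmax(0, (ls - mat$ls0) / (mat$ls_ref - mat$ls0))
  active <- mat$sig_act_kpa * act * f_len
  passive <- ifelse(strain > 0, mat$sig_pas_kpa * (exp(mat$k_pas * strain) - 1), 0)
  list(active = active, passive = passive)
}

## Thick-wall tension factor g(z) = atanh(z)/z = 1 + z^2/3 + z^4/5 + ...
## Exact for a thick-walled sphere with homogeneous fiber stress.
thickwall_factor <- function(z) {
  z <- abs(z)
  ifelse(z < 1e-4, 1 + z^2 / 3, ifelse(z < 0.99, atanh(z) / z, atanh(0.99) / 0.99))
}

#' Midwall tension and transmural pressure from fiber stress
#'
#' Laplace balance for a thick spherical cap with homogeneous fiber
#' stress: tension `Tm = (Vw*sigma/(2*Am)) * g(z)` with
#' `z = 3*Cm*Vw/(2*Am)`, and transmural pressure `p = 2*Tm*Cm`. For a
#' closed sphere this reduces exactly to
#' `p = (sigma/3) * log(1 + Vw/Vcavity)`.
#'
#' @param sigma_f fiber stress (any pressure unit; output is in the same
#'   unit).
#' @param geom wall geometry list: `Am` midwall area (cm^2), `Cm` midwall
#'   curvature (1/cm), `Vw` wall volume (mL).
#' @return list with tension `Tm` (pressure*cm) and transmural pressure
#'   `p_trans` (same pressure unit as `sigma_f`), positive when the wall
#'   compresses the concave (cavity) side.
#' @export
wall_pressure_from_stress <- function(sigma_f, geom) {
  z <- 3 * geom$Cm * geom$Vw / (2 * geom$Am)
  Tm <- geom$Vw * sigma_f / (2 * geom$Am) * thickwall_factor(z)
  list(Tm = Tm, p_trans = 2 * Tm * geom$Cm)
}

#' Spherical-cap geometry from cap volume and junction radius
#'
#' A cap with signed height `x` over a junction circle of radius `y`
#' encloses signed midwall volume `Vm = (pi/6) x (x^2 + 3 y^2)`; its area
#' is `Am = pi (x^2 + y^2)` and curvature `Cm = 2x/(x^2 + y^2)`. The cubic
#' in `x` is monotone and solved in closed form.
#'
#' @param Vm signed midwall cap volume, mL.
#' @param y junction radius, cm.
#' @return list `x`, `Am`, `Cm`, and junction tension direction cosines
#'   `sin_a`, `cos_a`.
#' @export
cap_geometry <- function(Vm, y) {
  cc <- 3 * Vm / pi # x^3 + 3 y^2 x - 6 Vm / pi = 0, half-coefficient form
  disc <- sqrt(cc^2 + y^6)
  x <- sign(cc + disc) * abs(cc + disc)^(1 / 3) + sign(cc - disc) * abs(cc - disc)^(1 / 3)
  s <- x^2 + y^2
  list(x = x, Am = pi * s, Cm = 2 * x / s,
       sin_a = 2 * x * y / s, cos_a = (y^2 - x^2) / s)
}

## Natural midwall fiber strain from wall geometry (area ratio with
## thickness correction terms).
wall_strain <- function(Am, Am_ref, z) {
  0.5 * log(Am / Am_ref) - z^2 / 12 - 0.019 * z^4
}

## Linear force-velocity factor on active stress: shortening (strain
## decreasing at rate s, 1/s) de-rates force as 1 - s/v_max; slight boost
## when lengthening, clamped.
force_velocity_factor <- function(eps, eps_prev, dt, v_max) {
  if (is.null(eps_prev) || is.null(dt) || dt <= 0) return(1)
  s <- (eps_prev - eps) / dt # positive when shortening
  min(max(1 - s / v_max, 0), 1.3)
}

## Evaluate one wall at a given cap geometry: strain, stress (kPa ->
## mmHg), tension and junction force components.
wall_tension_state <- function(Vm, y, Vw, Am_ref, mat, act, min_area = 1e-3,
                               eps_prev = NULL, dt = NULL) {
  g <- cap_geometry(Vm, y)
  Am <- max(g$Am, min_area)
  z <- 3 * g$Cm * Vw / (2 * Am)
  eps <- wall_strain(Am, Am_ref, z)
  b <- mat$strain_bounds
  if (eps < b[1] || eps > b[2])
    stop("segment_stress: strain out of physiologic bounds in wall")
  comp <- segment_stress_components(eps, act, mat)
  fv <- force_velocity_factor(eps, eps_prev, dt,
                              if (is.null(mat$v_max)) 3 else mat$v_max)
  sig_kpa <- comp$active * fv + comp$passive
  sig <- kpa_to_mmhg(sig_kpa)
  Tm <- Vw * sig / (2 * Am) * thickwall_factor(z)
  list(x = g$x, Am = Am, Cm = g$Cm, z = z, eps = eps,
       sigma_mmhg = sig, sigma_kpa = sig_kpa, Tm = Tm,
       Tx = Tm * g$sin_a, Ty = Tm * g$cos_a)
}

#' Solve the TriSeg junction equilibrium
#'
#' Finds the septal cap volume and junction radius such that the axial and
#' radial components of the three wall tensions balance at the junction.
#' Cap volumes of the free walls follow from the cavity volumes; a damped
#' Newton iteration with a finite-difference Jacobian is used, warm-started
#' from the previous time step.
#'
#' @param V_lv,V_rv ventricular cavity volumes, mL.
#' @param walls list with elements `LV`, `S`, `RV`, each carrying `Vw`
#'   (mL), `Am_ref` (cm^2) and `mat` (material list).
#' @param act named activation levels for `LV`, `S`, `RV`.
#' @param guess numeric c(VmS, y) starting point.
#' @param tol relative junction residual tolerance.
#' @param max_iter maximum Newton iterations.
#' @param eps_prev optional named vector of each wall's strain at the
#'   previous time step, enabling the force-velocity de-rating of active
#'   stress.
#' @param dt time step used with `eps_prev`, s.
#' @return list with the solution (`VmS`, `y`), per-wall states
#'   (`LV`, `S`, `RV`), transmural pressures of the free walls
#'   (`p_lv_trans`, `p_rv_trans`, positive = cavity above surroundings),
#'   fiber stresses in mmHg, and the final relative residual.
#' @export
triseg_solve <- function(V_lv, V_rv, walls, act, guess = c(40, 3.5),
                         tol = 1e-8, max_iter = 50, eps_prev = NULL, dt = NULL) {
  shift_l <- V_lv + 0.5 * walls$LV$Vw + 0.5 * walls$S$Vw
  shift_r <- V_rv + 0.5 * walls$RV$Vw + 0.5 * walls$S$Vw

  residual <- function(u) {
    VmS <- u[1]; y <- u[2]
    wl <- wall_tension_state(VmS - shift_l, y, walls$LV$Vw, walls$LV$Am_ref,
                             walls$LV$mat, act[["LV"]],
                             eps_prev = eps_prev[["LV"]], dt = dt)
    ws <- wall_tension_state(VmS, y, walls$S$Vw, walls$S$Am_ref,
                             walls$S$mat, act[["S"]],
                             eps_prev = eps_prev[["S"]], dt = dt)
    wr <- wall_tension_state(VmS + shift_r, y, walls$RV$Vw, walls$RV$Am_ref,
                             walls$RV$mat, act[["RV"]],
                             eps_prev = eps_prev[["RV"]], dt = dt)
    list(res = c(wl$Tx + ws$Tx + wr$Tx, wl$Ty + ws$Ty + wr$Ty),
         scale = abs(wl$Tm) + abs(ws$Tm) + abs(wr$Tm) + 1e-9,
         walls = list(LV = wl, S = ws, RV = wr))
  }

  newton <- function(u0) {
    u <- u0
    st <- residual(u)
    for (it in seq_len(max_iter)) {
      rel <- max(abs(st$res)) / st$scale
      if (rel < tol || max(abs(st$res)) < 1e-10)
        return(list(u = u, st = st, it = it, ok = TRUE))
      h <- c(max(1e-6, 1e-6 * abs(u[1])), max(1e-7, 1e-6 * abs(u[2])))
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        up <- u; up[j] <- up[j] + h[j]
        J[, j] <- (residual(up)$res - st$res) / h[j]
      }
      step <- tryCatch(solve(J, -st$res), error = function(e) NULL)
      if (is.null(step)) {
        ok <- max(abs(st$res)) / st$scale < 1e-5 || max(abs(st$res)) < 1e-8
        return(list(u = u, st = st, it = it, ok = ok))
      }
      lambda <- 1
      improved <- FALSE
      while (lambda >= 1e-5) {
        un <- u + lambda * step
        un[2] <- max(un[2], 0.3) # junction radius stays physical
        stn <- tryCatch(residual(un), error = function(e) NULL)
        if (!is.null(stn) &&
            max(abs(stn$res)) < max(abs(st$res)) * (1 - 0.1 * lambda) + 1e-12) {
          u <- un; st <- stn; improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!improved) # stalled from this start
        return(list(u = u, st = st, it = it,
                    ok = max(abs(st$res)) / st$scale < 1e-4))
    }
    list(u = u, st = st, it = max_iter,
         ok = max(abs(st$res)) / st$scale < 1e-4)
  }

  starts <- list(guess, c(40, 3.5), c(10, 3.0), c(70, 4.0), c(-20, 3.2))
  sol <- NULL
  for (s in starts) {
    sol <- newton(s)
    if (sol$ok) break
  }
  if (!sol$ok)
    stop(sprintf("triseg_solve: no convergence (relative residual %.3g at VmS=%.3g, y=%.3g)",
                 max(abs(sol$st$res)) / sol$st$scale, sol$u[1], sol$u[2]))
  u <- sol$u; st <- sol$st; it <- sol$it
  rel <- max(abs(st$res)) / st$scale
  w <- st$walls
  list(VmS = u[1], y = u[2], walls = w,
       p_lv_trans = -2 * w$LV$Tm * w$LV$Cm,
       p_rv_trans = 2 * w$RV$Tm * w$RV$Cm,
       sigma_mmhg = c(LV = w$LV$sigma_mmhg, S = w$S$sigma_mmhg, RV = w$RV$sigma_mmhg),
       residual = rel, iterations = it)
}

#' Spherical chamber (atrial) wall state
#'
#' Single-wall closed chamber: midwall sphere of volume
#' `Vcav + Vw/2`, with the same stress law and thick-wall Laplace balance
#' as the ventricular walls.
#'
#' @param V_cav cavity volume, mL.
#' @param wall list with `Vw`, `Am_ref`, `mat`.
#' @param act activation level.
#' @return list with transmural pressure (mmHg), fiber stress, geometry.
#' @export
chamber_state <- function(V_cav, wall, act, eps_prev = NULL, dt = NULL) {
  Vm <- V_cav + 0.5 * wall$Vw
  rm <- (3 * Vm / (4 * pi))^(1 / 3)
  Am <- 4 * pi * rm^2
  Cm <- 1 / rm
  z <- 3 * Cm * wall$Vw / (2 * Am)
  eps <- wall_strain(Am, wall$Am_ref, z)
  comp <- segment_stress_components(eps, act, wall$mat)
  fv <- force_velocity_factor(eps, eps_prev, dt,
                              if (is.null(wall$mat$v_max)) 3 else wall$mat$v_max)
  sig <- kpa_to_mmhg(comp$active * fv + comp$passive)
  lp <- wall_pressure_from_stress(sig, list(Am = Am, Cm = Cm, Vw = wall$Vw))
  list(p_trans = lp$p_trans, sigma_mmhg = sig, eps = eps, Am = Am, Cm = Cm)
}

#' Pericardial pressure from total pericardial volume
#'
#' Non-linearly compliant pericardium: approximately zero pressure at the
#' reference volume, rising steeply (convex) above it:
#' \eqn{p = s[(V/V_{ref})^k - 1]}.
#'
#' @param V total pericardial content (cavities + walls + epicardial
#'   coronary blood), mL.
#' @param V_ref reference pericardial volume, mL.
#' @param s pressure scale, mmHg.
#' @param k stiffness exponent.
#' @return pressure, mmHg.
#' @export
pericardial_pressure <- function(V, V_ref, s = 0.5, k = 10) {
  s * ((V / V_ref)^k - 1)
}
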