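## Cardiac-to-coronary coupling: transmurally varying intramyocardial
## pressure (IMP) built from cavity-induced extracellular pressure (CEP)
## and a fiber-stress-proportional stiffness component (VE).

#' Cavity-induced extracellular pressure at a transmural depth
#'
#' Tissue pressure transmitted from the adjacent cavity, varying linearly
#' across the wall: \eqn{CEP = r P_1 + (1-r) P_2} with `r` the radial
#' position measured from the outer (epicardial or, for the septum, RV)
#' side toward the cavity. For the free walls `P1` is the adjacent cavity
#' pressure and `P2` the pericardial pressure; for the septum `P1` is LV
#' and `P2` RV pressure, so the LV-facing subendocardium (r = 5/6)
#' approaches LV pressure.
#'
#' @param r radial position in (0, 1); layers sit at 1/6, 3/6, 5/6.
#' @param P1 endocardial-side (cavity) pressure, mmHg.
#' @param P2 epicardial-side pressure (pericardial, or RV for the septum),
#'   mmHg.
#' @return pressure, mmHg.
#' @export
cep <- function(r, P1, P2) r * P1 + (1 - r) * P2

#' Stiffness (varying elastance) component of intramyocardial pressure
#'
#' Proportional to the local total (active + passive) myofiber stress:
#' \eqn{VE = \gamma \sigma_f}. With the default \eqn{\gamma = 0.06} the
#' peak VE is about 20% of peak LV pressure. Applied uniformly over the
#' three transmural layers of a segment.
#'
#' @param sigma_f total fiber stress, mmHg (convert from kPa at the
#'   module boundary with [kpa_to_mmhg()]).
#' @param gamma dimensionless scaling (default 0.06, shared by LV, RV and
#'   septal walls).
#' @return pressure, mmHg.
#' @export
ve <- function(sigma_f, gamma = 0.06) gamma * sigma_f

#' Volume-weighted branch intramyocardial pressure
#'
#' Averages per-segment IMP over the segments of a branch's territory,
#' weighted by segment wall volume (equivalently mass, at uniform
#' density).
#'
#' @param imp_segments numeric vector of per-segment IMP, mmHg.
#' @param weights segment wall volumes (or masses) within the territory;
#'   normalized internally.
#' @return weighted mean IMP, mmHg.
#' @export
branch_imp <- function(imp_segments, weights) {
  if (length(weights) == 0 || sum(weights) <= 0)
    stop("branch_imp: empty territory")
  if (length(imp_segments) != length(weights))
    stop("branch_imp: segments and weights differ in length")
  sum(imp_segments * weights) / sum(weights)
}

#' Intramyocardial pressure per branch and layer
#'
#' Combines wall-level CEP (using each wall's adjacent pressures) and VE
#' (from each wall's fiber stress) into per-branch, per-layer IMP using
#' the coronary territory mass weights.
#'
#' @param r_layers radial layer positions (subepi, mid, subendo).
#' @param p_lv,p_rv,p_peri LV cavity, RV cavity and pericardial pressures,
#'   mmHg.
#' @param sigma_f named vector of wall fiber stresses (`LV`, `S`, `RV`),
#'   mmHg.
#' @param territory 3x3 mass-weight matrix, rows = branches (LCx, LAD,
#'   RCA), columns = walls (RV, S, LV), entries = territory mass in g.
#' @param gamma VE scaling.
#' @return matrix branches x layers of IMP, mmHg.
#' @export
imp_branch_layers <- function(r_layers, p_lv, p_rv, p_peri, sigma_f,
                              territory, gamma = 0.06) {
  nb <- nrow(territory)
  out <- matrix(0, nb, length(r_layers),
                dimnames = list(rownames(territory),
                                c("subepi", "mid", "subendo")))
  for (j in seq_along(r_layers)) {
    r <- r_layers[j]
    imp_wall <- c(
      RV = cep(r, p_rv, p_peri) + ve(sigma_f[["RV"]], gamma),
      S  = cep(r, p_lv, p_rv) + ve(sigma_f[["S"]], gamma),
      LV = cep(r, p_lv, p_peri) + ve(sigma_f[["LV"]], gamma)
    )
    for (b in seq_len(nb)) {
      w <- territory[b, ]
      out[b, j] <- branch_imp(imp_wall[colnames(territory)], w)
    }
  }
  out
}
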