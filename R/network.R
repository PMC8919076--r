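## Closed-loop network topology, wall segmentation and coronary territory
## assignment.

#' Wall specification with segment subdivision
#'
#' The LV free wall and septum are subdivided into 12 and 5 segments
#' (matching the 17-segment convention used for territory assignment);
#' the RV free wall is a single segment. Segment mass fractions default
#' to uniform and must sum to one.
#'
#' @param name wall name ("LV", "S" or "RV").
#' @param wall_volume_mL wall volume, mL.
#' @param n_segments number of segments.
#' @param segment_mass_fractions optional fractions (default uniform).
#' @param density_g_ml myocardial density, g/mL.
#' @return a `wall_spec` list with wall mass in g.
#' @export
wall_spec <- function(name, wall_volume_mL, n_segments,
                      segment_mass_fractions = NULL, density_g_ml = 1.055) {
  if (is.null(segment_mass_fractions))
    segment_mass_fractions <- rep(1 / n_segments, n_segments)
  if (length(segment_mass_fractions) != n_segments)
    stop("wall_spec: need one mass fraction per segment")
  if (abs(sum(segment_mass_fractions) - 1) > 1e-12)
    stop("wall_spec: segment mass fractions must sum to 1")
  structure(list(
    name = name,
    wall_volume_mL = wall_volume_mL,
    n_segments = n_segments,
    segment_mass_fractions = segment_mass_fractions,
    mass_g = wall_volume_mL * density_g_ml
  ), class = "wall_spec")
}

#' Per-branch coronary territory masses
#'
#' Each branch's territory mass is the sum over walls of the wall's mass
#' times the branch's territory fraction of that wall.
#'
#' @param walls list of `wall_spec` objects named RV, S, LV.
#' @param table branch x wall fraction matrix (see [territory_matrix()]).
#' @return named vector of branch masses, g; sums to total ventricular
#'   mass.
#' @export
territory_masses <- function(walls, table) {
  wall_mass <- vapply(colnames(table), function(w) walls[[w]]$mass_g, 0)
  for (w in colnames(table)) {
    if (abs(sum(table[, w]) - 1) > 1e-9)
      stop("territory_masses: fractions for wall ", w, " do not sum to 1")
  }
  drop(table %*% wall_mass)
}

#' Build and validate the reference closed-loop topology
#'
#' Assembles the fixed element graph of the model (chambers, valves,
#' conduit vessels, beds) with the geometry from the configuration, and
#' validates it: every element's upstream and downstream ends must attach
#' to declared elements (closed loop), vessel names must be unique, the
#' left main must bifurcate into exactly two daughters, each coronary
#' artery must terminate in a bed, and the coronary sinus must drain into
#' the right atrium.
#'
#' @param cfg validated configuration list.
#' @return a `coro_network` list with element tables, the territory mass
#'   matrix (g), and per-branch territory masses.
#' @export
build_reference_network <- function(cfg) {
  vn <- names(cfg$vessels)
  if (anyDuplicated(vn)) stop("configuration error: duplicate vessel name: ",
                              vn[duplicated(vn)][1])
  needed <- c("sys_art", "sys_ven", "pul_art", "pul_ven", "LM", "LAD", "LCx",
              "RCA", "v_LAD", "v_LCx", "v_RCA", "cs_dist", "cs_prox")
  missing <- setdiff(needed, vn)
  if (length(missing)) stop("configuration error: missing vessel: ",
                            paste(missing, collapse = ", "))

  edges <- rbind(
    data.frame(from = "LA", to = "LV", via = "mitral", kind = "valve"),
    data.frame(from = "LV", to = "sys_art", via = "aortic", kind = "valve"),
    data.frame(from = "sys_art", to = "sys_ven", via = "systemic_bed", kind = "bed"),
    data.frame(from = "sys_ven", to = "RA", via = "vc_inlet", kind = "inlet"),
    data.frame(from = "RA", to = "RV", via = "tricuspid", kind = "valve"),
    data.frame(from = "RV", to = "pul_art", via = "pulmonary", kind = "valve"),
    data.frame(from = "pul_art", to = "pul_ven", via = "pulmonary_bed", kind = "bed"),
    data.frame(from = "pul_ven", to = "LA", via = "pv_inlet", kind = "inlet"),
    data.frame(from = "sys_art", to = "LM", via = "junction", kind = "tube"),
    data.frame(from = "sys_art", to = "RCA", via = "junction", kind = "tube"),
    data.frame(from = "LM", to = "LAD", via = "junction", kind = "tube"),
    data.frame(from = "LM", to = "LCx", via = "junction", kind = "tube"),
    data.frame(from = "LAD", to = "v_LAD", via = "LAD_bed", kind = "coronary_bed"),
    data.frame(from = "LCx", to = "v_LCx", via = "LCx_bed", kind = "coronary_bed"),
    data.frame(from = "RCA", to = "v_RCA", via = "RCA_bed", kind = "coronary_bed"),
    data.frame(from = "v_LAD", to = "cs_dist", via = "junction", kind = "tube"),
    data.frame(from = "v_LCx", to = "cs_dist", via = "junction", kind = "tube"),
    data.frame(from = "cs_dist", to = "cs_prox", via = "junction", kind = "tube"),
    data.frame(from = "v_RCA", to = "cs_prox", via = "junction", kind = "tube"),
    data.frame(from = "cs_prox", to = "RA", via = "cs_ostium", kind = "inlet")
  )

  nodes <- union(edges$from, edges$to)
  dangling <- setdiff(nodes, c("LA", "RA", "LV", "RV", vn))
  if (length(dangling)) stop("configuration error: unconnected node: ",
                             paste(dangling, collapse = ", "))
  ## closed loop: every element must have at least one inflow and one outflow
  for (el in nodes) {
    if (!el %in% edges$to) stop("configuration error: no inflow into ", el)
    if (!el %in% edges$from) stop("configuration error: no outflow from ", el)
  }
  lm_children <- edges$to[edges$from == "LM"]
  if (length(lm_children) != 2) stop("configuration error: LM must bifurcate")
  if (!"RA" %in% edges$to[edges$from == "cs_prox"])
    stop("configuration error: coronary sinus must drain into RA")

  walls <- list(
    LV = wall_spec("LV", cfg$walls$LV$wall_volume_mL, cfg$walls$LV$n_segments,
                   cfg$walls$LV$segment_mass_fractions, cfg$walls$density_g_ml),
    S = wall_spec("S", cfg$walls$S$wall_volume_mL, cfg$walls$S$n_segments,
                  cfg$walls$S$segment_mass_fractions, cfg$walls$density_g_ml),
    RV = wall_spec("RV", cfg$walls$RV$wall_volume_mL, cfg$walls$RV$n_segments,
                   cfg$walls$RV$segment_mass_fractions, cfg$walls$density_g_ml)
  )
  tt <- territory_matrix(cfg)
  masses <- territory_masses(walls, tt)
  wall_mass <- vapply(colnames(tt), function(w) walls[[w]]$mass_g, 0)
  mass_matrix <- tt * rep(wall_mass, each = nrow(tt)) # branch x wall, g

  structure(list(
    edges = edges,
    vessels = vn,
    coronary_arteries = c("LM", "LAD", "LCx", "RCA"),
    coronary_veins = c("v_LAD", "v_LCx", "v_RCA", "cs_dist", "cs_prox"),
    walls = walls,
    territory_fractions = tt,
    territory_mass = mass_matrix,
    branch_mass_g = masses
  ), class = "coro_network")
}

#' @export
print.coro_network <- function(x, ...) {
  cat("Closed-loop cardiovascular network\n")
  cat(sprintf("  %d conduit vessels (%d coronary arteries, %d coronary veins)\n",
              length(x$vessels), length(x$coronary_arteries),
              length(x$coronary_veins)))
  cat(sprintf("  ventricular mass %.1f g; territories: %s\n",
              sum(x$branch_mass_g),
              paste(sprintf("%s %.1f g", names(x$branch_mass_g),
                            x$branch_mass_g), collapse = ", ")))
  invisible(x)
}
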