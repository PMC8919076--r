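test_that("volume-dependent resistance follows the inverse-square law", {
  expect_equal(poiseuille_resistance(2, 10, 2), 10) # V = V0
  expect_equal(poiseuille_resistance(1, 10, 2), 40) # half volume, 4x
  expect_equal(poiseuille_resistance(4, 10, 2), 2.5) # double volume, /4
  ## finite in the collapse regime thanks to the volume floor
  expect_true(is.finite(poiseuille_resistance(0, 10, 2)))
})

test_that("reference resistance network reproduces the split arithmetic", {
  rr <- reference_resistances(83, 90, 0, endo_epi = 1.11)
  expect_equal(rr$R_total, 90 / (83 / 60), tolerance = 1e-12) # ~65.06
  expect_equal(rr$R_a, 0.28 * rr$R_total)
  expect_equal(rr$R_v, 0.07 * rr$R_total)
  ## layer arteriolar resistances recombine in parallel to 60% of the
  ## intramyocardial block
  expect_equal(1 / sum(1 / rr$layers$R1), 0.60 * 0.65 * rr$R_total,
               tolerance = 1e-12)
  expect_equal(1 / sum(1 / (rr$layers$R1 + rr$layers$Rm + rr$layers$R2)),
               0.65 * rr$R_total, tolerance = 1e-12)
  ## layer flows honour the endo-to-epi ratio and sum to the target
  q <- setNames(rr$layers$q0, rr$layers$layer)
  expect_equal(q[["subendo"]] / q[["subepi"]], 1.11)
  expect_equal(q[["mid"]], (q[["subepi"]] + q[["subendo"]]) / 2)
  expect_equal(sum(q), 83 / 60)
  expect_error(reference_resistances(83, 10, 50), "perfusion pressure")
  expect_error(reference_resistances(83, 90, 0, splits_main = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

make_test_bed <- function(...) {
  build_bed("LAD", 65.8, 83, p_art = 91, p_ven = 4,
            micro = default_config()$coronary_micro)
}

test_that("bed derivatives conserve mass and vanish at uniform pressure", {
  bed <- make_test_bed()
  ## equilibrium: choose volumes so every compartment sits at one common
  ## pressure, with matching boundary pressures and no tissue pressure
  pstar <- 30
  V <- vapply(seq_len(8), function(i) {
    cp <- bed$comp[i, ]
    stats::uniroot(function(v) tube_law_pressure(v / cp$L, cp$p0, cp$A0,
                                                 cp$Aw, cp$k) - pstar,
                   c(1e-4, 10 * cp$V0), tol = 1e-12)$root
  }, 0)
  md <- micro_derivatives(bed, V, p_in = pstar, Z_in = 2, p_out = pstar,
                          Z_out = 1, p_im = c(0, 0, 0), p_peri = 0)
  expect_lt(max(abs(md$dV)), 1e-8)
  expect_lt(max(abs(c(md$q_in, md$q_out, md$q1, md$qm, md$q2))), 1e-8)

  ## Kirchhoff: at any state the bed stores exactly inflow minus outflow
  V2 <- bed$comp$V0 * c(1.1, 0.9, 1.2, 0.8, 1.05, 0.95, 1.15, 0.85)
  md2 <- micro_derivatives(bed, V2, 95, 2, 6, 1,
                           p_im = c(5, 30, 80), p_peri = 1)
  expect_equal(sum(md2$dV), md2$q_in - md2$q_out, tolerance = 1e-12)
})

test_that("a subendocardial tissue-pressure step drives retrograde arteriolar flow", {
  bed <- make_test_bed()
  V0 <- bed$comp$V0
  base <- micro_derivatives(bed, V0, 91, 2, 4, 1, p_im = c(0, 0, 0), p_peri = 0)
  step <- micro_derivatives(bed, V0, 91, 2, 4, 1, p_im = c(0, 0, 90), p_peri = 0)
  expect_lt(step$q1[3], 0) # subendo arteriolar flow reverses
  ## subepicardial flow barely changes
  expect_lt(abs(step$q1[1] - base$q1[1]) / abs(base$q1[1]), 0.05)
  ## venular outflow of the squeezed layer increases
  expect_gt(step$q2[3], base$q2[3])
})

test_that("driven bed settles at the reference operating point without tissue pressure", {
  ## chain-anchored bed: with boundary pressures compensated for the
  ## inlet/outlet wave-impedance drops at target flow, the steady state
  ## is V = V0 with layer flows at target
  rig <- make_driven_bed_fixture(peak_lv_pressure = 0, p_ven = 4,
                                 p0_mode = "chain", Z_in = 0.05, Z_out = 0.05)
  cp <- rig$bed$comp
  q0_tot <- rig$bed$q0
  Za <- wave_impedance(cp$A0[1], cp$p0[1], cp$A0[1], cp$Aw[1], cp$k[1])
  Zv <- wave_impedance(cp$A0[8], cp$p0[8], cp$A0[8], cp$Aw[8], cp$k[8])
  rig$p_art <- rig$p_art + q0_tot * (rig$Z_in + Za)
  rig$p_ven <- rig$p_ven - q0_tot * (rig$Z_out + Zv)
  out <- run_bed_fixture(rig, n_beats = 40)
  q_mean <- colMeans(out$q1)
  q0 <- rig$bed$layer_q0
  expect_equal(unname(q_mean), unname(q0), tolerance = 0.02)
  expect_equal(unname(out$V[nrow(out$V), ]), unname(rig$bed$comp$V0),
               tolerance = 0.02)
})

test_that("quasi-static tissue-pressure sweep monotonically compresses arterioles", {
  bed <- make_test_bed()
  V <- bed$comp$V0
  pim_grid <- seq(0, 120, by = 20)
  v_endo <- numeric(length(pim_grid))
  for (j in seq_along(pim_grid)) {
    ## relax to the static state at this tissue pressure
    for (i in 1:4000) {
      md <- micro_derivatives(bed, V, 91, 2, 4, 1,
                              p_im = rep(pim_grid[j], 3), p_peri = 0)
      V <- V + 0.001 * md$dV
    }
    v_endo[j] <- V[4] # subendo arteriolar compartment
  }
  expect_true(all(diff(v_endo) < 0))
})

test_that("compartment diameter scales with the square root of volume", {
  expect_equal(compartment_diameter(81, 100), 0.9)
  expect_equal(compartment_diameter(2, 2, d_ref = 3), 3)
})
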