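test_that("territory masses reproduce the reference arithmetic", {
  ## wall masses 114 / 47 / 41 g with the standard territory fractions
  walls <- list(
    LV = wall_spec("LV", 114, 12, density_g_ml = 1),
    S = wall_spec("S", 47, 5, density_g_ml = 1),
    RV = wall_spec("RV", 41, 1, density_g_ml = 1)
  )
  tt <- territory_matrix(default_config())
  m <- territory_masses(walls, tt)
  expect_equal(m[["RCA"]], 41 + 0.40 * 47 + 0.25 * 114) # 88.3
  expect_equal(m[["LAD"]], 0.60 * 47 + 0.33 * 114) # 65.82
  expect_equal(m[["LCx"]], 0.42 * 114) # 47.88
  expect_equal(sum(m), 114 + 47 + 41)

  ## identity fraction: one branch owning a whole wall gets its full mass
  tt2 <- tt
  tt2[, "LV"] <- c(1, 0, 0)
  expect_equal(territory_masses(walls, tt2)[["LCx"]], 114)

  tt_bad <- tt
  tt_bad["RCA", "RV"] <- 0.5
  expect_error(territory_masses(walls, tt_bad), "sum to 1")
})

test_that("wall mass follows volume times myocardial density within rounding", {
  lv <- wall_spec("LV", 108, 12, density_g_ml = 1.055)
  expect_equal(lv$mass_g, 113.94)
  expect_equal(round(lv$mass_g), 114)
  expect_error(wall_spec("LV", 108, 12, segment_mass_fractions = rep(0.1, 12)),
               "sum to 1")
  expect_error(wall_spec("LV", 108, 12, segment_mass_fractions = c(0.5, 0.5)),
               "one mass fraction per segment")
})

test_that("reference network builds with the published vessel complement", {
  net <- build_reference_network(default_config())
  expect_length(net$coronary_arteries, 4) # LM, LAD, LCx, RCA
  expect_length(net$coronary_veins, 5) # 3 branch veins + distal/proximal CS
  expect_s3_class(net, "coro_network")
  ## LM bifurcates into LAD and LCx
  kids <- net$edges$to[net$edges$from == "LM"]
  expect_setequal(kids, c("LAD", "LCx"))
  ## coronary sinus drains into the right atrium
  expect_true(any(net$edges$from == "cs_prox" & net$edges$to == "RA"))
})

test_that("configuration errors name the offending element", {
  cfg <- default_config()
  cfg$vessels$LM <- NULL
  expect_error(build_reference_network(cfg), "missing vessel: LM")
})

test_that("the closed loop conserves volume instantaneously and over a beat", {
  cfg <- default_config()
  sim <- new_sim(cfg)
  vol_idx <- c(sim$idx$V_cav, sim$idx$V_tube, sim$idx$V_bed)
  ## Kirchhoff closure at t = 0: signed node flows sum to zero
  core <- coroflow:::compute_core(sim, sim$x, 0)
  expect_lt(abs(sum(core$dx[vol_idx])), 1e-10)
  ## over a full beat the total blood volume drifts by < 1e-6 of itself
  tot0 <- sum(sim$x[vol_idx])
  run_beat(sim)
  tot1 <- sum(sim$x[vol_idx])
  expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
})
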