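vent_mat <- default_config()$mechanics$ventricle_mat

test_that("fiber stress is passive-only at zero activation and monotone in strain", {
  expect_equal(segment_stress(0, 0, vent_mat), 0) # zero-stress reference
  expect_gt(segment_stress(0.1, 0, vent_mat), 0) # stretched, passive only
  comp <- segment_stress_components(0.1, 0, vent_mat)
  expect_equal(comp$active, 0)
  s <- vapply(seq(-0.1, 0.2, by = 0.02), segment_stress, 0, act = 0.7,
              mat = vent_mat)
  expect_true(all(diff(s) > 0)) # monotone in strain at fixed activation
  expect_error(segment_stress(2, 0.5, vent_mat), "bounds")
  expect_error(segment_stress(0.1, 1.5, vent_mat), "activation")
})

test_that("Laplace balance matches the thick-sphere closed form to 1e-10", {
  for (case in list(c(Vw = 108, V = 80, sig = 300), c(Vw = 39, V = 120, sig = 90),
                    c(Vw = 200, V = 40, sig = 500))) {
    Vm <- case[["V"]] + case[["Vw"]] / 2
    rm <- (3 * Vm / (4 * pi))^(1 / 3)
    geom <- list(Am = 4 * pi * rm^2, Cm = 1 / rm, Vw = case[["Vw"]])
    p <- wall_pressure_from_stress(case[["sig"]], geom)$p_trans
    oracle <- case[["sig"]] / 3 * log(1 + case[["Vw"]] / case[["V"]])
    expect_equal(p, oracle, tolerance = 1e-10)
  }
  ## zero stress gives zero pressure; pressure is linear in stress
  geom <- list(Am = 120, Cm = 0.3, Vw = 100)
  expect_equal(wall_pressure_from_stress(0, geom)$p_trans, 0)
  expect_equal(wall_pressure_from_stress(2 * 250, geom)$p_trans,
               2 * wall_pressure_from_stress(250, geom)$p_trans)
})

test_that("spherical cap geometry inverts its own volume formula", {
  for (Vm in c(-80, -20, 15, 60)) {
    g <- cap_geometry(Vm, y = 3.2)
    expect_equal(pi / 6 * g$x * (g$x^2 + 3 * 3.2^2), Vm, tolerance = 1e-9)
    expect_equal(g$sin_a^2 + g$cos_a^2, 1, tolerance = 1e-12)
  }
})

test_that("TriSeg equilibrium: symmetric loading flattens the septum, LV loading bows it right", {
  cfg <- default_config()
  walls <- list(
    LV = list(Vw = 80, Am_ref = 95, mat = vent_mat),
    S = list(Vw = 80, Am_ref = 95, mat = vent_mat),
    RV = list(Vw = 80, Am_ref = 95, mat = vent_mat)
  )
  sym <- triseg_solve(110, 110, walls, c(LV = 0.3, S = 0.3, RV = 0.3))
  expect_lt(abs(sym$VmS), 1) # flat septum under symmetric loading
  expect_lt(sym$residual, 1e-8) # junction residual below solver tolerance

  ## higher left-sided load bows the septum toward the RV (VmS > 0),
  ## higher right-sided load bows it leftward
  left <- triseg_solve(160, 70, walls, c(LV = 0.3, S = 0.3, RV = 0.3))
  right <- triseg_solve(70, 160, walls, c(LV = 0.3, S = 0.3, RV = 0.3))
  expect_gt(left$VmS, 1)
  expect_lt(right$VmS, -1)
  expect_gt(left$p_lv_trans, left$p_rv_trans)

  ## with the real wall volumes and systolic activation, LV pressure
  ## exceeds RV pressure and the septum bulges rightward
  sim_walls <- new_sim(cfg)$walls
  sys <- triseg_solve(90, 100, sim_walls, c(LV = 0.9, S = 0.9, RV = 0.9))
  expect_gt(sys$p_lv_trans, sys$p_rv_trans)
  expect_gt(sys$VmS, 0)
})

test_that("pericardial pressure anchors at the reference volume, rising convexly", {
  expect_equal(pericardial_pressure(700, 700), 0)
  V <- seq(600, 900, by = 25)
  p <- pericardial_pressure(V, 700)
  expect_true(all(diff(p) > 0)) # strictly increasing
  ## convex: secant slopes increase
  slopes <- diff(p) / diff(V)
  expect_true(all(diff(slopes) > 0))
})

test_that("activation is periodic with the configured duration and onset", {
  period <- 60 / 71
  dur <- 0.41 * period
  expect_equal(activation(0, period, dur), 0)
  expect_gt(activation(dur / 2, period, dur), 0.99)
  expect_equal(activation(dur + 1e-6, period, dur), 0, tolerance = 1e-6)
  ## periodicity
  expect_equal(activation(0.2, period, dur), activation(0.2 + 3 * period, period, dur))
  ## onset shift wraps across the cycle boundary
  a <- activation(0.01, period, 0.2, onset = period - 0.17)
  expect_gt(a, 0) # atrial twitch continuing past the cycle wrap
})

test_that("force-velocity factor de-rates shortening and caps lengthening", {
  expect_equal(force_velocity_factor(0.1, NULL, 0.001, 3), 1)
  expect_lt(force_velocity_factor(0.099, 0.1, 0.001, 3), 1) # shortening
  expect_gt(force_velocity_factor(0.101, 0.1, 0.001, 3), 1) # lengthening
  expect_equal(force_velocity_factor(0.0, 0.1, 0.001, 3), 0) # clamped at 0
})
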