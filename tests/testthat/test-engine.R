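## Engine-level behaviour on short simulations (a few beats from the
## standard initial state; full steady-state runs live in the acceptance
## tests).

test_that("identical configurations give bit-identical beats", {
  cfg <- default_config()
  s1 <- new_sim(cfg)
  s2 <- new_sim(cfg)
  r1 <- run_beat(s1)
  r2 <- run_beat(s2)
  expect_identical(r1$M, r2$M)
  expect_identical(s1$x, s2$x)
})

test_that("closed valves carry no flow against an adverse gradient", {
  sim <- new_sim(default_config())
  for (i in 1:3) rec <- run_beat(sim)
  M <- rec$M
  ## whenever the aortic valve is closed, flow is exactly zero even
  ## though the aorta is above LV pressure
  closed <- M[, "q_av"] == 0
  expect_gt(sum(closed), 100)
  expect_true(all(M[closed, "q_av"] == 0))
  expect_gt(mean(M[closed, "p_sys_art"] - M[closed, "p_lv"]), 0)
  ## no regurgitation anywhere
  expect_true(all(M[, c("q_mv", "q_av", "q_tv", "q_pv")] >= 0))
})

test_that("halving the step changes the end state consistently with a first-order scheme", {
  cfg <- default_config()
  err <- vapply(c(1e-3, 5e-4), function(dt) {
    cfg$solver$dt_s <- dt
    sim <- new_sim(cfg)
    run_beat(sim)
    cfg$solver$dt_s <- 2.5e-4
    ref <- new_sim(cfg)
    run_beat(ref)
    ## compare volume states only (valve flows switch discontinuously)
    vol <- c(sim$idx$V_cav, sim$idx$V_tube, sim$idx$V_bed)
    max(abs(sim$x[vol] - ref$x[vol]) / pmax(abs(ref$x[vol]), 1))
  }, 0)
  ratio <- err[1] / err[2]
  expect_gt(ratio, 1.3) # error shrinks with dt
  expect_lt(ratio, 6) # at roughly first order
})

test_that("stroke work computed from the cavity record is positive", {
  sim <- new_sim(default_config())
  rec <- NULL
  for (i in 1:8) rec <- run_beat(sim)
  M <- rec$M
  work <- -sum(M[, "p_lv"] * c(diff(M[, "V_lv"]), 0)) # mmHg*mL, loop integral
  expect_gt(work, 1000) # of order 7500 mmHg*mL = 1 J in a healthy beat
})

test_that("scenario overrides touch only the declared key and revert cleanly", {
  cfg <- default_config()
  sten <- new_sim(cfg, "aortic_stenosis")
  refc <- new_sim(cfg, "reference")
  expect_equal(sten$cfg$valves$aortic$A_open_cm2, 0.8)
  cfg2 <- sten$cfg
  cfg2$valves$aortic$A_open_cm2 <- 4.8
  expect_equal(cfg2, refc$cfg)
})
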