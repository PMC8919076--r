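## synthetic phase object: n samples, systole = given index range
make_phases <- function(n, sys_idx, i_ED = 1L) {
  sys <- logical(n)
  sys[sys_idx] <- TRUE
  list(sys = sys, i_ED = i_ED, i_ES = max(sys_idx), i_open = min(sys_idx))
}

test_that("pDSVR is the plateau max ratio on synthetic waveforms", {
  n <- 300
  ph <- make_phases(n, 1:100)
  v <- c(rep(0.10, 100), rep(0.25, 200)) # m/s plateaus
  expect_equal(pdsvr(v, ph), 2.5)
  expect_equal(pdsvr(rep(0.2, n), ph), 1.0) # constant velocity
  expect_warning(r <- pdsvr(c(rep(-0.1, 100), rep(0.2, 200)), ph), "systolic")
  expect_true(is.na(r))
})

test_that("DTVi uses the clipped antegrade integral convention", {
  n <- 300
  ph <- make_phases(n, 1:100)
  ## equal plateaus, diastole twice as long as systole -> 2/3
  v <- rep(0.2, n)
  expect_equal(dtvi(v, ph), 2 / 3)
  ## zero diastolic velocity -> 0
  v2 <- c(rep(0.2, 100), rep(0, 200))
  expect_equal(dtvi(v2, ph), 0)
  ## retrograde systolic flow is clipped, not subtracted
  v3 <- c(rep(-0.2, 100), rep(0.2, 200))
  expect_equal(dtvi(v3, ph), 1)
  expect_true(dtvi(v3, ph) >= 0 && dtvi(v3, ph) <= 1)
  expect_warning(r <- dtvi(rep(-1, n), ph), "antegrade")
  expect_true(is.na(r))
})

test_that("diameter change follows the square-root volume convention", {
  n <- 200
  ph <- make_phases(n, 50:120, i_ED = 1L)
  V <- rep(1, n)
  V[120] <- 0.81 # V_ES = 0.81 V_ED -> d ratio 0.9 -> -10%
  expect_equal(diameter_change_ed_es(V, ph), -10)
  expect_equal(diameter_change_ed_es(rep(2, n), ph), 0)
})

test_that("retrograde fraction splits the signed integral", {
  expect_equal(retrograde_fraction(c(1, 1, -1, 1)), 0.25)
  expect_equal(retrograde_fraction(rep(0.3, 10)), 0)
  expect_equal(retrograde_fraction(numeric(0)), 0)
})

test_that("metric functions are pure (bit-identical on repeated evaluation)", {
  set.seed(7)
  v <- sin(seq(0, 2 * pi, length.out = 500)) + 0.3
  ph <- make_phases(500, 40:240)
  expect_identical(pdsvr(v, ph), pdsvr(v, ph))
  expect_identical(dtvi(v, ph), dtvi(v, ph))
})
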