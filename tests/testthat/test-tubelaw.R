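test_that("tube law anchors at the reference area and collapses at small areas", {
  for (k in c(8, 10, 12)) {
    expect_equal(tube_law_pressure(2, 45, 2, 2, k), 45) # Aw = A0: exact anchor
    expect_equal(tube_law_pressure(1.5, 20, 1.5, 0.3 * 1.5, k), 20) # Aw < A0
  }
  ## progressively negative toward collapse
  expect_lt(tube_law_pressure(0.01, 45, 1, 1, 12), 0)
  p <- tube_law_pressure(c(0.05, 0.02, 0.01), 45, 1, 1, 12)
  expect_true(all(diff(p) < 0))
  expect_error(tube_law_pressure(0, 45, 1, 1, 12), "positive")
})

test_that("analytic tube-law slope matches a finite-difference derivative", {
  cases <- expand.grid(A = c(0.3, 0.8, 1, 1.6), aw = c(0.3, 1), k = c(8, 12))
  h <- 1e-7
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; aw <- cases$aw[i]; k <- cases$k[i]
    fd <- (tube_law_pressure(A + h, 45, 1, aw, k) -
             tube_law_pressure(A - h, 45, 1, aw, k)) / (2 * h)
    an <- tube_law_dpda(A, 45, 1, aw, k)
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("wave speed follows the linearised tube-law slope", {
  A <- 4.8; p0 <- 91; k <- 8
  c_num <- wave_speed(A, p0, A, A, k)
  dpda <- tube_law_dpda(A, p0, A, A, k)
  c_ref <- sqrt(A * 1e-4 * dpda * 133.322387415e4 / 1050)
  expect_equal(c_num, c_ref, tolerance = 1e-10)
  ## small-amplitude pulse speed: secant slope of the law reproduces the
  ## analytic speed within 2%
  dA <- 0.01 * A
  dpda_sec <- (tube_law_pressure(A + dA, p0, A, A, k) -
                 tube_law_pressure(A - dA, p0, A, A, k)) / (2 * dA)
  expect_equal(sqrt(A * 1e-4 * dpda_sec * 133.322e4 / 1050), c_num,
               tolerance = 0.02)
})

test_that("impedance scales as rho*c/A and junction reflections behave", {
  Z1 <- wave_impedance(1, 45, 1, 1, 8)
  c1 <- wave_speed(1, 45, 1, 1, 8)
  expect_equal(Z1, 1050 * c1 / 1e-4 / 133.322387415 * 1e-6, tolerance = 1e-12)
  ## halving A at fixed wave speed doubles Z
  expect_equal((1050 * c1 / (0.5 * 1e-4)) / (1050 * c1 / 1e-4), 2)
  ## matched tubes do not reflect; a closed end reflects fully
  expect_equal(junction_reflection(Z1, Z1), 0)
  expect_equal(junction_reflection(Z1, Inf), 1)
  expect_lt(junction_reflection(Z1, Z1 / 3), 0) # opening: negative reflection
})
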