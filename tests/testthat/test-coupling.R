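test_that("cavity-induced extracellular pressure is the affine transmural blend", {
  expect_equal(cep(5 / 6, 110, 0), 110 * 5 / 6) # 91.67 at the subendocardium
  expect_equal(cep(1 / 2, 87, 13), 50) # midwall average
  expect_equal(cep(0.3, 42, 42), 42) # degenerate gradient
  ## endocardial and epicardial limits
  expect_equal(cep(1, 110, 5), 110)
  expect_equal(cep(0, 110, 5), 5)
})

test_that("stiffness component is linear in fiber stress and gamma", {
  expect_equal(ve(0, 0.06), 0)
  expect_equal(ve(300, 0.06), 18)
  expect_equal(ve(300, 0.12), 2 * ve(300, 0.06))
  expect_true(all(ve(c(0, 10, 400), 0.06) >= 0))
})

test_that("branch IMP is the volume-weighted segment average", {
  expect_equal(branch_imp(c(50, 50, 50), c(1, 2, 3)), 50)
  expect_equal(branch_imp(c(40, 80), c(1, 1)), 60)
  expect_error(branch_imp(numeric(0), numeric(0)), "empty territory")
  expect_error(branch_imp(c(1, 2), c(1, 2, 3)), "length")
})

test_that("branch-layer IMP honours transmural ordering and territory bounds", {
  territory <- rbind(LCx = c(RV = 0, S = 0, LV = 47.9),
                     LAD = c(RV = 0, S = 28.2, LV = 37.6),
                     RCA = c(RV = 41, S = 18.8, LV = 28.5))
  r <- c(1 / 6, 3 / 6, 5 / 6)
  sig <- c(LV = 300, S = 280, RV = 120)
  imp <- imp_branch_layers(r, p_lv = 110, p_rv = 25, p_peri = 2, sig,
                           territory, gamma = 0.06)
  ## subendo >= mid >= subepi for every branch when P1 >= P2
  for (b in rownames(imp)) {
    expect_true(imp[b, "subendo"] >= imp[b, "mid"])
    expect_true(imp[b, "mid"] >= imp[b, "subepi"])
  }
  ## RCA mixes RV and left-sided segments: strictly between the pure cases
  pure_rv <- cep(5 / 6, 25, 2) + ve(sig[["RV"]], 0.06)
  pure_lv <- cep(5 / 6, 110, 2) + ve(sig[["LV"]], 0.06)
  expect_gt(imp["RCA", "subendo"], pure_rv)
  expect_lt(imp["RCA", "subendo"], pure_lv)
  ## RCA IMP below the left branches (RV pressure << LV pressure)
  expect_lt(max(imp["RCA", ]), max(imp["LAD", ]))
  ## gamma = 0 reduces to pure CEP; P1 = P2 = 0 reduces to pure VE
  imp0 <- imp_branch_layers(r, 110, 25, 2, sig, territory, gamma = 0)
  expect_equal(imp0["LCx", "subendo"], cep(5 / 6, 110, 2))
  impv <- imp_branch_layers(r, 0, 0, 0, sig, territory, gamma = 0.06)
  expect_equal(impv["LCx", "mid"], ve(sig[["LV"]], 0.06))
})
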