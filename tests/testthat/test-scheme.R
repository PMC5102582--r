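moderate <- deriveScheme(K1 = 0.15, K2 = 200, gamma = 125, K5 = 0.5)
severe <- deriveScheme(K1 = 1, K2 = 200, gamma = 2500, K5 = 10)
wt <- deriveScheme(K1 = 0.01, K2 = 200, gamma = 25, K5 = 0.1)
study <- mixtureTotals(PT = 50, LT = 150)

test_that("deriveScheme closes the thermodynamic cycle", {
  expect_equal(moderate@K3, 25000)
  expect_equal(moderate@K4, 0.004)
  sev2 <- deriveScheme(K1 = 1, K2 = 200, gamma = 2500, K5 = 10)
  expect_equal(sev2@K3, 5e5)
  expect_equal(sev2@K4, 0.004)
  unit <- deriveScheme(1, 1, 1, 1)
  expect_equal(unit@K3, 1)
  expect_equal(unit@K4, 1)
  # cycle closure invariant K4/K5 = K2/K3 = 1/gamma
  expect_equal(moderate@K4 / moderate@K5, moderate@K2 / moderate@K3,
               tolerance = 1e-12)
  expect_error(deriveScheme(-1, 200, 25, 0.1), "K1")
  expect_error(deriveScheme(1, 0, 25, 0.1), "K2")
})

test_that("ligand quadratic coefficients follow the mass-balance algebra", {
  q <- ligandQuadratic(moderate, study)
  # frozen from independent direct arithmetic on the printed constants
  expect_equal(q$alpha, 0.15 / 1.15, tolerance = 1e-12)
  expect_equal(q$sigma_sum, 0.1052666666667, tolerance = 1e-10)
  expect_equal(q$A, 0.0137304347826, tolerance = 1e-10)
  expect_equal(q$B, -0.3730434782609, tolerance = 1e-10)
  expect_equal(q$C, -150)
  # zero ligand and matched totals
  expect_equal(ligandQuadratic(moderate, mixtureTotals(50, 0))$C, 0)
  expect_equal(ligandQuadratic(moderate, mixtureTotals(50, 50))$B, 1)
})

test_that("free-ligand root matches the bisection oracle", {
  L <- solveFreeLigand(ligandQuadratic(moderate, study))
  expect_equal(L, 118.9846219806, tolerance = 1e-9)
  expect_equal(L, bruteSpeciate(0.15, 200, 125, 0.5, 50, 150)$L,
               tolerance = 1e-9)
  Ls <- solveFreeLigand(ligandQuadratic(severe, study))
  expect_equal(Ls, 129.7395573, tolerance = 1e-7)
  expect_equal(solveFreeLigand(ligandQuadratic(moderate,
                                               mixtureTotals(50, 0))), 0)
  # residual of the quadratic vanishes at the root
  q <- ligandQuadratic(moderate, study)
  expect_lt(abs(q$A * L^2 + q$B * L + q$C) / study$LT, 1e-12)
})

test_that("speciation reproduces the locked and apparent-up fractions", {
  sp <- speciate(moderate, study)
  expect_equal(fLocked(sp), 0.392848360, tolerance = 1e-8)
  expect_equal(pUApparent(sp), 0.078988728, tolerance = 1e-8)
  expect_equal(fLocked(speciate(severe, study)), 0.019291985,
               tolerance = 1e-8)
  # no ligand: pure conformational equilibrium
  sp0 <- speciate(moderate, mixtureTotals(50, 0))
  expect_equal(unname(species(sp0)[c("UV", "DV", "DH", "DHV")]),
               rep(0, 4))
  expect_equal(pUApparent(sp0), 0.15 / 1.15, tolerance = 1e-12)
})

test_that("mass balance, root uniqueness and the Kd identity hold on random draws", {
  set.seed(42)
  for (i in 1:1000) {
    p <- randomScheme()
    PT <- stats::runif(1, 1, 500)
    LT <- stats::runif(1, 0.1, 1000)
    sp <- speciate(p, mixtureTotals(PT, LT))
    s <- species(sp)
    expect_lt(abs(sum(s) - PT) / PT, 1e-9)
    expect_lt(abs(freeLigand(sp) + sum(s[c("UV", "DV", "DH", "DHV")]) -
                  LT) / LT, 1e-9)
    # equilibrium ratios reproduce the defining constants
    expect_equal(s[["U"]] / s[["D"]], p@K1, tolerance = 1e-9)
    expect_equal(s[["U"]] * freeLigand(sp) / s[["UV"]], p@K2,
                 tolerance = 1e-9)
    expect_equal(s[["DV"]] / s[["DHV"]], p@K5, tolerance = 1e-9)
    # Eq.-5 closed form equals the species-ratio definition
    kd <- kdMacro(p, mixtureTotals(PT, LT))
    kd_ratio <- (s[["D"]] + s[["U"]] + s[["DH"]]) * freeLigand(sp) /
      (s[["UV"]] + s[["DV"]] + s[["DHV"]])
    expect_lt(abs(kd - kd_ratio) / kd, 1e-10)
  }
  # quadratic root agrees with the independent bisection oracle
  set.seed(7)
  for (i in 1:25) {
    K1 <- exp(stats::runif(1, log(0.01), log(10)))
    K2 <- exp(stats::runif(1, log(1), log(1000)))
    g <- exp(stats::runif(1, log(1), log(5000)))
    K5 <- exp(stats::runif(1, log(0.01), log(100)))
    PT <- stats::runif(1, 1, 500); LT <- stats::runif(1, 0.1, 1000)
    p <- deriveScheme(K1, K2, g, K5)
    L <- solveFreeLigand(ligandQuadratic(p, mixtureTotals(PT, LT)))
    expect_equal(L, bruteSpeciate(K1, K2, g, K5, PT, LT)$L,
                 tolerance = 1e-9)
  }
})

test_that("macroscopic Kd evaluates to the class values and limits", {
  expect_equal(kdMacro(wt, study), 18.7367106, tolerance = 1e-7)
  expect_equal(kdMacro(moderate, study), 73.3180562, tolerance = 1e-7)
  expect_equal(kdMacro(severe, study), 190.5009028, tolerance = 1e-7)
  expect_error(kdMacro(wt, mixtureTotals(50, 0)), "LT = 0")
  expect_equal(kdMacroLimit(wt, "wt"), 20)
  expect_equal(kdMacroLimit(wt, "severe"), 200)
  expect_equal(kdMacroLimit(deriveScheme(0.01, 1, 25, 1), "wt"), 1)
  expect_error(kdMacroLimit(wt, "mild"))
})

test_that("Kd,macro is monotone in K5 and converges to the VIM-only model", {
  k5s <- c(0.05, 0.1, 0.5, 2, 10, 50)
  kds <- vapply(k5s, function(k5)
    kdMacro(deriveScheme(0.15, 200, 25 * k5 / 0.1, k5), study), 0)
  flks <- vapply(k5s, function(k5)
    fLocked(speciate(deriveScheme(0.15, 200, 25 * k5 / 0.1, k5), study)), 0)
  expect_true(all(diff(kds) >= 0))
  expect_true(all(diff(flks) <= 0))
  # K5 -> Inf with gamma prop. K5: H1/H2 pathway shuts off, VIM-only
  big <- deriveScheme(0.15, 200, 25 * 1e8, 1e7 * 0.1)
  sp <- speciate(big, study)
  expect_lt(fLocked(sp), 1e-6)
  expect_equal(pUApparent(sp), 0.15 / 1.15, tolerance = 1e-5)
  L <- freeLigand(sp)
  expect_equal(kdMacro(big, study), 200, tolerance = 1e-4)
})

test_that("mutant class table reproduces the simulation scenario", {
  tab <- mutantClassTable()
  expect_equal(tab$class, c("wt", "moderate", "severe"))
  expect_equal(tab$kd_macro_uM, c(18.7367106, 73.3180562, 190.5009028),
               tolerance = 1e-6)
  expect_equal(tab$f_locked[tab$class == "moderate"], 0.392848360,
               tolerance = 1e-7)
  tab0 <- mutantClassTable(totals = mixtureTotals(50, 0))
  expect_equal(tab0$pU_apparent,
               c(0.01 / 1.01, 0.15 / 1.15, 0.5), tolerance = 1e-12)
})
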