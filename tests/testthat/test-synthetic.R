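test_that("generators are deterministic under a fixed seed", {
  n <- defaultNoise()
  expect_identical(genShiftSeries(noise = n, seed = 9),
                   genShiftSeries(noise = n, seed = 9))
  m <- data.frame(reporter = "m1", s2_axis = 0.9, tau_c_ns = 91,
                  delta_density = 100)
  expect_identical(genBuildup(m, noise_sd = 0.01, seed = 9),
                   genBuildup(m, noise_sd = 0.01, seed = 9))
  p <- data.frame(residue = 1:3, tau_c_ns = 13.6, s2 = 0.85, tau_e_ps = 50)
  expect_identical(genN15(p, noise_frac = 0.02, seed = 9),
                   genN15(p, noise_frac = 0.02, seed = 9))
  sc <- schemeScenario()$wt
  expect_identical(genTitration(sc, noise = n, seed = 9),
                   genTitration(sc, noise = n, seed = 9))
  expect_error(genShiftSeries(noise = n), "seed")
})

test_that("noise-free shift series is exactly inverted by estimatePU", {
  pu <- c(wt = 0, a = 0.13, b = 0.14, c = 0.42, d = 0.56, ATPgS = 1)
  tab <- genShiftSeries(variants = pu, noise = NULL)
  out <- estimatePopulations(tab)
  per <- out$per_reporter
  for (v in c("a", "b", "c", "d"))
    expect_equal(per$pU[per$variant == v], rep(pu[[v]],
                 sum(per$variant == v)), tolerance = 1e-12)
  expect_equal(out$per_variant$pU_sd, rep(0, 4), tolerance = 1e-12)
  # pU = 0 reproduces the down endpoints exactly
  wt_rows <- tab[tab$variant == "wt", ]
  i189 <- defaultReporterModels()$I189
  expect_equal(wt_rows$delta_c_ppm[wt_rows$residue == 189],
               unname(i189$delta_D["c"]))
})

test_that("buildup generator round-trips through the fitter", {
  m <- data.frame(reporter = c("a", "b"), s2_axis = c(1, 0.8),
                  tau_c_ns = 91, delta_density = c(0, 120))
  curves <- genBuildup(m, delays = buildupDelays("long"))
  # tau_c = 91 ns with S2 = 1 saturates near the 0.75 asymptote at 50 ms
  a50 <- curves[curves$reporter == "a" & curves$delay_s == 0.05, ]
  expect_gt(a50$ratio, 0.7)
  fits <- fitBuildupTable(curves)$fits
  expect_equal(fits$s2tau_ns[fits$reporter == "a"], 91, tolerance = 1e-5)
  expect_equal(fits$s2tau_ns[fits$reporter == "b"], 0.8 * 91,
               tolerance = 1e-5)
  # slower tumbling gives uniformly larger ratios at every delay
  fast <- genBuildup(data.frame(reporter = "f", s2_axis = 0.9,
                                tau_c_ns = 13, delta_density = 20))
  slow <- genBuildup(data.frame(reporter = "s", s2_axis = 0.9,
                                tau_c_ns = 91, delta_density = 20))
  expect_true(all(slow$ratio > fast$ratio))
})

test_that("15N generator matches the limiting relations", {
  # zero offset puts the spin lock on resonance: R1rho equals R2
  p <- data.frame(residue = 1, tau_c_ns = 13.6, s2 = 0.85, tau_e_ps = 50)
  rec <- genN15(p, 600, offset_hz = 0)
  rates <- n15Rates(13.6, 0.85, 50, 600)
  expect_equal(rec$r1rho, rates[["r2"]], tolerance = 1e-12)
  # S2 = 1 collapses to the single-Lorentzian rates for any tau_e
  r_a <- n15Rates(13.6, 1, 0, 600)
  r_b <- n15Rates(13.6, 1, 500, 600)
  expect_equal(r_a, r_b, tolerance = 1e-12)
})

test_that("titration generator honours the speciation limits", {
  sc <- schemeScenario()$wt
  reps <- defaultReporterModels()
  tab <- genTitration(sc, PT = 50, LT_grid = c(0, 50, 150, 5e4),
                      reporters = reps)
  # zero ligand reproduces the free-state shifts
  v68_0 <- tab[tab$reporter == "V68" & tab$ligand_total_uM == 0, ]
  expect_equal(v68_0$delta_h_ppm, unname(reps$V68$delta_D["h"]))
  # saturating ligand drives VIM probes to the bound shift and
  # equilibrium probes to their locked shift
  v68_s <- tab[tab$reporter == "V68" & tab$ligand_total_uM == 5e4, ]
  expect_equal(v68_s$delta_h_ppm, unname(reps$V68$delta_vim["h"]),
               tolerance = 1e-2)
  i146_s <- tab[tab$reporter == "I146" & tab$ligand_total_uM == 5e4, ]
  expect_equal(i146_s$delta_c_ppm, unname(reps$I146$delta_lock["c"]),
               tolerance = 1e-2)
  expect_error(genTitration(sc, LT_grid = c(50, 150)), "zero-ligand")
})

test_that("scheme-generated titrations fit back to the macroscopic Kd", {
  sc <- schemeScenario()$wt
  grid <- c(0, 12.5, 25, 50, 100, 150, 250)
  vimReps <- c("V68", "V108", "I175")
  kd_ref <- kdMacro(sc, mixtureTotals(50, 150))
  # noise-free: the single-Kd isotherm approximates the six-state
  # titration of VIM-site probes to within a few percent at
  # mid-titration (the macroscopic Kd varies slowly with free ligand)
  tab <- genTitration(sc, PT = 50, LT_grid = grid)
  vim <- tab[tab$reporter %in% vimReps, ]
  f0 <- fitTitration(titrationSeries(vim, PT = 50))
  expect_lt(abs(f0@kd - kd_ref) / kd_ref, 0.05)
  # noisy, fixed seed: the estimate agrees with the noise-free fit
  # within its own reported uncertainty
  tabn <- genTitration(sc, PT = 50, LT_grid = grid,
                       noise = defaultNoise(), seed = 31)
  vimn <- tabn[tabn$reporter %in% vimReps, ]
  fn <- fitTitration(titrationSeries(vimn, PT = 50))
  expect_lt(abs(fn@kd - f0@kd), 3 * fn@se)
})
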