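test_that("pU follows from linear interpolation and 2-D projection", {
  ep <- twoStateEndpoints(c(c = 13.00), c(c = 14.00))
  expect_equal(estimatePU(ep, 13.42)$pU, 0.42)
  expect_equal(estimatePU(ep, 13.00)$pU, 0)
  expect_equal(estimatePU(ep, 14.00)$pU, 1)
  # 2-D: midway on the segment with a pure perpendicular offset
  ep2 <- twoStateEndpoints(c(h = 0.50, c = 20.0), c(h = 0.70, c = 20.0))
  est <- estimatePU(ep2, c(h = 0.60, c = 20.0 + 0.01 / 0.25))
  expect_equal(est$pU, 0.5)
  expect_equal(est$deviation_ppm, 0.01, tolerance = 1e-12)
  expect_false(est$flagged)
  # out-of-range values are flagged, never clamped
  far <- estimatePU(ep, 14.5)
  expect_equal(far$pU, 1.5)
  expect_true(far$flagged)
  expect_error(twoStateEndpoints(c(c = 13.0), c(c = 13.0)), "degenerate")
})

test_that("pU is invariant under consistent affine rescaling of the axis", {
  set.seed(3)
  for (i in 1:20) {
    dD <- stats::runif(1, 10, 20); dU <- dD + stats::runif(1, 0.2, 2)
    p <- stats::runif(1)
    dm <- (1 - p) * dD + p * dU
    a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, -5, 5)
    ep1 <- twoStateEndpoints(c(c = dD), c(c = dU))
    ep2 <- twoStateEndpoints(c(c = a * dD + b), c(c = a * dU + b))
    expect_equal(estimatePU(ep1, dm)$pU,
                 estimatePU(ep2, a * dm + b)$pU, tolerance = 1e-9)
  }
})

test_that("aggregation matches the multi-reporter consistency check", {
  a <- aggregatePU(c(I189 = 0.14, L229 = 0.13, M388 = 0.13))
  expect_equal(a$mean, mean(c(0.14, 0.13, 0.13)))
  expect_equal(a$sd, stats::sd(c(0.14, 0.13, 0.13)))
  b <- aggregatePU(c(0.42, 0.56, 0.45))
  expect_equal(b$mean, 0.4766667, tolerance = 1e-6)
  single <- aggregatePU(0.42)
  expect_equal(single$mean, 0.42)
  expect_true(is.na(single$sd))
  # flagged estimates are excluded and listed
  agg <- aggregatePU(c(a = 0.4, b = 0.45, c = 1.4))
  expect_equal(agg$n, 2)
  expect_equal(agg$excluded, "c")
  expect_error(aggregatePU(list()), "no estimates")
})

test_that("collinearity flags off-segment variants", {
  ep <- twoStateEndpoints(c(h = 0.50, c = 13.0), c(h = 0.70, c = 14.0))
  pu <- c(0, 0.3, 0.7, 1)
  traj <- data.frame(variant = letters[1:4],
                     delta_h_ppm = 0.50 + 0.20 * pu,
                     delta_c_ppm = 13.0 + 1.0 * pu)
  res <- collinearity(traj, ep)
  expect_equal(res$deviation_ppm, rep(0, 4), tolerance = 1e-12)
  expect_false(any(res$flagged))
  expect_true(attr(res, "monotonic"))
  # one variant pushed 0.05 ppm perpendicular to the segment
  seg <- c(0.20, 0.25)  # scaled-space direction
  perp <- c(-seg[2], seg[1]) / sqrt(sum(seg^2)) * 0.05
  traj$delta_h_ppm[2] <- traj$delta_h_ppm[2] + perp[1]
  traj$delta_c_ppm[2] <- traj$delta_c_ppm[2] + perp[2] / 0.25
  res2 <- collinearity(traj, ep)
  expect_equal(res2$deviation_ppm[2], 0.05, tolerance = 1e-9)
  expect_equal(which(res2$flagged), 2L)
  expect_error(collinearity(traj[1:2, ], ep), "at least 3")
})

test_that("noisy synthetic trajectories stay collinear and ordered", {
  set.seed(19)
  pu <- c(0, 0.14, 0.42, 1.0)
  ep <- twoStateEndpoints(c(h = 0.75, c = 13.0), c(h = 0.55, c = 14.0))
  traj <- data.frame(variant = c("wt", "R155H", "R95G", "ATPgS"),
                     delta_h_ppm = 0.75 - 0.20 * pu +
                       stats::rnorm(4, 0, 0.002),
                     delta_c_ppm = 13.0 + 1.0 * pu +
                       stats::rnorm(4, 0, 0.002))
  res <- collinearity(traj, ep)
  expect_false(any(res$flagged))
  expect_true(attr(res, "monotonic"))
})

test_that("free-energy conversion is antisymmetric and matches printed populations", {
  expect_equal(deltaG(0.14), 1165.713, tolerance = 1e-6)
  expect_equal(deltaG(0.42), 207.2733, tolerance = 1e-6)
  expect_equal(deltaG(0.5), 0)
  p <- c(0.1, 0.25, 0.6, 0.9)
  expect_equal(deltaG(p) + deltaG(1 - p), rep(0, 4))
  expect_true(all(diff(deltaG(seq(0.05, 0.95, by = 0.05))) < 0))
  expect_error(deltaG(0), "strictly between")
  expect_error(deltaG(1), "strictly between")
})

test_that("fast-exchange bound scales with field and shift difference", {
  b <- exchangeBound(d_delta_h = 0, d_delta_c = 1.0, field_h_mhz = 800)
  expect_equal(b, 2 * pi * 800 * 0.25145, tolerance = 1e-12)
  expect_equal(exchangeBound(0, 1.0, 1600), 2 * b)
  # a zero nucleus is ignored; the larger bound wins
  both <- exchangeBound(d_delta_h = 0.3, d_delta_c = 1.0,
                        field_h_mhz = 800)
  expect_equal(both, max(2 * pi * 0.3 * 800, b))
  expect_error(exchangeBound(0, 0, 800), "undefined")
})

test_that("CSP tables combine nuclei and respect join semantics", {
  a <- data.frame(residue = c(10, 20, 30), atom = "ILE-CD1",
                  delta_h_ppm = c(0.5, 0.7, 0.9),
                  delta_c_ppm = c(12, 13, 14))
  expect_equal(cspTable(a, a)$combined, rep(0, 3))
  b <- a
  b$delta_h_ppm[1] <- b$delta_h_ppm[1] + 0.03
  b$delta_c_ppm[1] <- b$delta_c_ppm[1] + 0.40
  csp <- cspTable(a, b)
  expect_equal(csp$combined[1], sqrt(0.03^2 + 0.10^2), tolerance = 1e-12)
  # degenerate weight reduces to |d delta H|
  expect_equal(cspTable(a, b, w_c = 0)$combined[1], 0.03)
  # symmetric up to sign of the per-nucleus deltas
  rev <- cspTable(b, a)
  expect_equal(rev$d_delta_h, -csp$d_delta_h)
  expect_equal(rev$combined, csp$combined)
  # unmatched reporters are listed, not dropped silently
  bb <- b[-2, ]
  expect_equal(attr(cspTable(a, bb), "unmatched"), "20|ILE-CD1")
  expect_error(cspTable(a, data.frame(residue = 99, atom = "MET-CE",
                                      delta_h_ppm = 1, delta_c_ppm = 1)),
               "no reporters shared")
})

test_that("CSP classification uses a strict threshold and domain ranges", {
  rec <- data.frame(residue = c(50, 150, 200, 250, 300, 400),
                    atom = "ILE-CD1",
                    d_delta_h = 0,
                    d_delta_c = 0,
                    combined = c(0.35, 0.31, 0.30, 0.6, 0.1, 0.45))
  hit <- classifyCsp(rec, threshold = 0.3)
  expect_equal(hit$residue, c(50, 150, 250, 400))  # 0.30 excluded: strict
  expect_equal(hit$domain, c("NTD", "NTD", "D1", "D1"))
  expect_equal(nrow(classifyCsp(rec, threshold = 1)), 0)
  # a linker residue labels as linker
  expect_equal(classifyCsp(data.frame(residue = 195, atom = "x",
                                      combined = 0.5))$domain, "linker")
})
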