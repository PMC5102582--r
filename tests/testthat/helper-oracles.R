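# Independent brute-force oracle for the six-state speciation: solve the
# ligand mass balance by bisection on the residual, reconstructing all
# species from a trial free-ligand value.  Shares no code with
# ligandQuadratic()/solveFreeLigand().
bruteSpeciate <- function(K1, K2, gamma, K5, PT, LT,
                          tol = 1e-13) {
  K3 <- gamma * K2
  K4 <- K5 / gamma
  speciesAt <- function(L) {
    # free protomer pool from protein mass balance given L
    denom <- 1 + 1 / K1 + L / K2 + L / (K1 * K2) + L / (K1 * K3) +
      L / (K1 * K3 * K4)
    U <- PT / denom
    D <- U / K1
    list(U = U, D = D, UV = U * L / K2, DV = D * L / K2,
         DH = D * L / K3, DHV = D * L / (K3 * K4))
  }
  residual <- function(L) {
    s <- speciesAt(L)
    L + s$UV + s$DV + s$DH + s$DHV - LT
  }
  lo <- 0; hi <- LT
  if (LT == 0) return(c(speciesAt(0), L = 0))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * LT) break
  }
  L <- (lo + hi) / 2
  c(speciesAt(L), L = L)
}

# random valid scheme parameters for property tests
randomScheme <- function() {
  deriveScheme(K1 = exp(stats::runif(1, log(0.01), log(10))),
               K2 = exp(stats::runif(1, log(1), log(1000))),
               gamma = exp(stats::runif(1, log(1), log(5000))),
               K5 = exp(stats::runif(1, log(0.01), log(100))))
}

# noise-free titration table from the plain single-site depletion
# isotherm (independent of the scheme machinery)
makeIsothermSeries <- function(kd, PT, LT_grid, reporters) {
  rows <- do.call(rbind, lapply(names(reporters), function(r) {
    fb <- (PT + LT_grid + kd -
           sqrt((PT + LT_grid + kd)^2 - 4 * PT * LT_grid)) / (2 * PT)
    dF <- reporters[[r]]["dF"]; dB <- reporters[[r]]["dB"]
    data.frame(reporter = r, ligand_total_uM = LT_grid,
               delta_h_ppm = dF + fb * (dB - dF),
               sigma_ppm = 1e-6, stringsAsFactors = FALSE)
  }))
  titrationSeries(rows, PT = PT)
}
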