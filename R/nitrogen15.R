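#' Back-calculate R2 from an off-resonance R1rho measurement
#'
#' Spin-lock relaxation mixes R1 and R2 through the tilt angle of the
#' effective field: \eqn{R_{1\rho} = R_2\sin^2\theta + R_1\cos^2\theta}
#' with \eqn{\tan\theta = \nu_1/\Delta}, where \eqn{\nu_1} is the
#' spin-lock field strength and \eqn{\Delta} the resonance offset from
#' the carrier.  Inverting gives
#' \eqn{R_2 = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta}.
#'
#' @param r1rho,r1 measured rates, s^-1.  Vectorized.
#' @param nu1_hz spin-lock field, Hz (> 0).
#' @param offset_hz offset from the carrier, Hz (0 gives R2 = R1rho).
#' @return R2 in s^-1.
#' @examples
#' r2FromR1rho(20, 2, nu1_hz = 1800, offset_hz = 1800 / tan(pi / 3))
#' @export
r2FromR1rho <- function(r1rho, r1, nu1_hz, offset_hz = 0) {
  if (any(nu1_hz <= 0)) stop("spin-lock field nu1 must be positive")
  theta <- atan2(nu1_hz, offset_hz)
  s2 <- sin(theta)^2
  (r1rho - r1 * cos(theta)^2) / s2
}

# Lipari-Szabo model-free spectral density, all times in seconds,
# J in s/rad
.jModelFree <- function(omega, tau_c, s2, tau_e) {
  tp <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) +
         (1 - s2) * tp / (1 + (omega * tp)^2))
}

# interaction constants for the 15N-1H spin pair
.n15Interaction <- function(field_h_mhz, r_nh_m = 1.02e-10,
                            csa_ppm = -160) {
  cst <- methylConstants()
  omega_h <- 2 * pi * field_h_mhz * 1e6
  omega_n <- omega_h * .GAMMA_N15 / .GAMMA_H1
  d <- cst$mu0_over_4pi * .GAMMA_H1 * .GAMMA_N15 * cst$hbar / r_nh_m^3
  c_csa <- omega_n * (csa_ppm * 1e-6) / sqrt(3)
  list(omega_h = omega_h, omega_n = omega_n, d2 = d^2, c2 = c_csa^2)
}

#' Forward model-free 15N relaxation rates
#'
#' Computes R1, R2 and the steady-state 15N-\{1H\} NOE from the
#' Lipari-Szabo spectral density
#' \eqn{J(\omega) = (2/5)[S^2\tau_c/(1+(\omega\tau_c)^2) +
#' (1-S^2)\tau'/(1+(\omega\tau')^2)]}, \eqn{1/\tau' = 1/\tau_c +
#' 1/\tau_e}, with N-H dipolar and 15N CSA contributions.  This is the
#' generator counterpart of [reducedJw()] and [modelFreeFit()] and uses
#' the same interaction constants.
#'
#' @param tau_c_ns overall tumbling time, ns.
#' @param s2 squared order parameter of the N-H bond vector.
#' @param tau_e_ps internal correlation time, ps.
#' @param field_h_mhz 1H spectrometer frequency, MHz.
#' @param r_nh_m N-H distance, m (default 1.02 Angstrom).
#' @param csa_ppm 15N chemical shift anisotropy, ppm (default -160).
#' @return named vector c(r1, r2, noe).
#' @export
n15Rates <- function(tau_c_ns, s2, tau_e_ps, field_h_mhz,
                     r_nh_m = 1.02e-10, csa_ppm = -160) {
  stopifnot(s2 >= 0, s2 <= 1, tau_c_ns > 0, tau_e_ps >= 0)
  k <- .n15Interaction(field_h_mhz, r_nh_m, csa_ppm)
  J <- function(w) .jModelFree(abs(w), tau_c_ns * 1e-9, s2, tau_e_ps * 1e-12)
  jn <- J(k$omega_n); jh <- J(k$omega_h)
  jhn_m <- J(k$omega_h - k$omega_n); jhn_p <- J(k$omega_h + k$omega_n)
  r1 <- k$d2 / 4 * (jhn_m + 3 * jn + 6 * jhn_p) + k$c2 * jn
  r2 <- k$d2 / 8 * (4 * J(0) + jhn_m + 3 * jn + 6 * jh + 6 * jhn_p) +
    k$c2 / 6 * (4 * J(0) + 3 * jn)
  noe <- 1 + (.GAMMA_H1 / .GAMMA_N15) * k$d2 / 4 *
    (6 * jhn_p - jhn_m) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

#' Reduced spectral density mapping
#'
#' Maps (R1, R2, NOE) at a single field into the spectral density at
#' three frequencies, \eqn{J(0)}, \eqn{J(\omega_N)} and
#' \eqn{J(0.87\omega_H)}, under the standard high-frequency-plateau
#' approximation \eqn{J(\omega_H-\omega_N) \approx J(\omega_H) \approx
#' J(\omega_H+\omega_N) \approx J(0.87\omega_H)}:
#' \deqn{\sigma_{NH} = R_1(NOE-1)\gamma_N/\gamma_H, \quad
#'   J(0.87\omega_H) = \frac{4\sigma_{NH}}{5d^2}}
#' then J(wN) from R1 and J(0) from R2.  A negative J(0) is flagged (the
#' `flagged` attribute), never silently clipped.
#'
#' @param r1,r2,noe measured rates (s^-1) and NOE; use [r2FromR1rho()]
#'   first when R2 was measured as R1rho.
#' @param field_h_mhz 1H frequency, MHz.
#' @param r_nh_m,csa_ppm interaction constants, as [n15Rates()].
#' @param high_freq_scale effective high-frequency multiplier (default
#'   0.87).
#' @return named vector c(j0, jwn, jwh) in ns/rad.
#' @export
reducedJw <- function(r1, r2, noe, field_h_mhz, r_nh_m = 1.02e-10,
                      csa_ppm = -160, high_freq_scale = 0.87) {
  k <- .n15Interaction(field_h_mhz, r_nh_m, csa_ppm)
  sigma_nh <- r1 * (noe - 1) * .GAMMA_N15 / .GAMMA_H1
  jwh <- 4 * sigma_nh / (5 * k$d2)
  jwn <- (r1 - 7 * k$d2 / 4 * jwh) / (3 * k$d2 / 4 + k$c2)
  j0 <- (r2 - k$d2 / 8 * (13 * jwh + 3 * jwn) - k$c2 / 2 * jwn) /
    (k$d2 / 2 + 2 * k$c2 / 3)
  out <- c(j0 = unname(j0), jwn = unname(jwn), jwh = unname(jwh)) * 1e9
  if (j0 < 0) {
    warning("negative J(0) from mapping; rates are inconsistent")
    attr(out, "flagged") <- TRUE
  }
  out
}

# fit (tau_c, s2, tau_e) to a mapped J triplet by coarse grid with
# closed-form S2 (J is linear in S2), then local refinement
.fitJTriplet <- function(jns, omegas, tau_bounds = c(1, 500),
                         taue_bounds = c(0, 1000)) {
  jobs <- jns * 1e-9
  w <- 1 / pmax(abs(jobs), 1e-12)^2     # relative weighting
  taus <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]),
                  length.out = 80)) * 1e-9
  taues <- c(0, exp(seq(log(0.5), log(max(taue_bounds[2], 1)),
                        length.out = 30))) * 1e-12
  best <- list(obj = Inf)
  for (tc in taus) for (te in taues) {
    tp <- if (te > 0) 1 / (1 / tc + 1 / te) else 0
    base <- 0.4 * tp / (1 + (omegas * tp)^2)
    slope <- 0.4 * tc / (1 + (omegas * tc)^2) - base
    s2 <- sum(w * slope * (jobs - base)) / sum(w * slope^2)
    s2 <- min(max(s2, 0), 1)
    resid <- base + s2 * slope - jobs
    obj <- sum(w * resid^2)
    if (obj < best$obj) best <- list(obj = obj, tc = tc, te = te, s2 = s2)
  }
  fn <- function(p) {
    jfit <- .jModelFree(omegas, exp(p[1]), p[2], exp(p[3]))
    sum(w * (jfit - jobs)^2)
  }
  opt <- stats::optim(
    c(log(best$tc), best$s2, log(max(best$te, 1e-15))), fn,
    method = "L-BFGS-B",
    lower = c(log(tau_bounds[1] * 1e-9), 0, log(1e-15)),
    upper = c(log(tau_bounds[2] * 1e-9), 1, log(taue_bounds[2] * 1e-12)),
    control = list(factr = 1e4, maxit = 500))
  s2 <- opt$par[2]
  tau_e_ps <- exp(opt$par[3]) * 1e12
  # when (1 - S2) vanishes tau_e has no leverage on J
  unidentifiable <- s2 > 0.995
  list(tau_c_ns = exp(opt$par[1]) * 1e9, s2 = s2,
       tau_e_ps = if (unidentifiable) NA_real_ else tau_e_ps,
       chisq = opt$value, tau_e_flagged = unidentifiable)
}

#' Per-residue model-free fit of 15N relaxation data
#'
#' For each residue: converts R1rho to R2 through the tilt-angle
#' relation, maps (R1, R2, NOE) to the reduced spectral-density triplet,
#' and fits the Lipari-Szabo parameters (tau_c, S2, tau_e) by a coarse
#' grid over (tau_c, tau_e) with closed-form S2 followed by bounded
#' local refinement.  The tumbling-time summary (mean +/- SD) is taken
#' over residues passing the structured filter.
#'
#' @param records data.frame with columns `residue`, `r1`, `r1rho`,
#'   `noe`, `field_h_mhz`, `nu1_hz`, `offset_hz`.
#' @param noe_min structured-residue filter on the NOE (default 0.60,
#'   appropriate at 600 MHz for a ~14 ns domain with tens-of-ps internal
#'   motion).
#' @param tau_bounds,taue_bounds fit bounds, ns and ps.
#' @param r_nh_m,csa_ppm interaction constants, as [n15Rates()].
#' @return list with `fits` (per-residue data.frame: tau_c_ns, s2,
#'   tau_e_ps, chisq, structured, tau_e_flagged) and `summary`
#'   (a [TauSummary-class] over structured residues).
#' @export
modelFreeFit <- function(records, noe_min = 0.60, tau_bounds = c(1, 500),
                         taue_bounds = c(0, 1000), r_nh_m = 1.02e-10,
                         csa_ppm = -160) {
  need <- c("residue", "r1", "r1rho", "noe", "field_h_mhz", "nu1_hz",
            "offset_hz")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("relaxation table lacks column(s): ", paste(miss, collapse = ", "))
  fits <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    r2 <- r2FromR1rho(rec$r1rho, rec$r1, rec$nu1_hz, rec$offset_hz)
    jns <- reducedJw(rec$r1, r2, rec$noe, rec$field_h_mhz,
                     r_nh_m = r_nh_m, csa_ppm = csa_ppm)
    k <- .n15Interaction(rec$field_h_mhz, r_nh_m, csa_ppm)
    omegas <- c(0, abs(k$omega_n), 0.87 * k$omega_h)
    fit <- .fitJTriplet(as.numeric(jns), omegas, tau_bounds, taue_bounds)
    data.frame(residue = rec$residue, tau_c_ns = fit$tau_c_ns,
               s2 = fit$s2, tau_e_ps = fit$tau_e_ps, chisq = fit$chisq,
               structured = rec$noe >= noe_min,
               tau_e_flagged = fit$tau_e_flagged)
  })
  fits <- do.call(rbind, fits)
  structured_tau <- fits$tau_c_ns[fits$structured]
  summary <- if (length(structured_tau) >= 5)
    tauHistogram(structured_tau) else NULL
  list(fits = fits, summary = summary)
}
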