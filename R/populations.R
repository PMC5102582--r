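#' Two-state endpoint shifts for a reporter
#'
#' Limiting chemical shifts of the down (D, from the wt-ADP state) and up
#' (U, from the wt-ATPgS state) NTD conformations, per nucleus.
#'
#' @param delta_D,delta_U named numeric `c(h = , c = )` in ppm (either
#'   nucleus may be NA when unmeasured).
#' @param floor minimum endpoint separation (ppm, after carbon scaling)
#'   below which the reporter is rejected as degenerate.
#' @param w_c carbon weight used for the separation check.
#' @return list of class `twoStateEndpoints`.
#' @export
twoStateEndpoints <- function(delta_D, delta_U, floor = 0.02, w_c = 0.25) {
  dD <- .asHC(delta_D); dU <- .asHC(delta_U)
  sep <- sqrt(sum((.scaleHC(dU - dD, w_c))^2, na.rm = TRUE))
  if (!is.finite(sep) || sep <= floor * w_c)
    stop("degenerate endpoints: |dU - dD| below the separation floor")
  structure(list(delta_D = dD, delta_U = dU, w_c = w_c),
            class = "twoStateEndpoints")
}

.asHC <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- c(c = unname(x))
  out <- c(h = NA_real_, c = NA_real_)
  out[names(x)] <- x
  out
}

.scaleHC <- function(x, w_c) {
  x * c(h = 1, c = w_c)[names(x)]
}

#' Up-state population from a population-averaged shift
#'
#' Under two-state fast exchange the observed shift is
#' \eqn{\delta_{obs} = p_D\,\delta_D + p_U\,\delta_U}, so with one
#' nucleus pU is linear interpolation between the endpoints.  With both
#' 1H and 13C shifts the observed point is projected orthogonally onto
#' the D-to-U segment in scaled 2-D shift space (carbon weighted by
#' `w_c`); the perpendicular distance off the segment is reported as a
#' linearity diagnostic.  pU is not clamped: values outside
#' \[-0.05, 1.05\] are flagged, since clamping would hide endpoint
#' errors.
#'
#' @param endpoints a [twoStateEndpoints()].
#' @param delta_obs observed shift(s): scalar (13C) or named
#'   `c(h = , c = )`, ppm.
#' @return list with `pU`, `pD`, `deviation_ppm` (perpendicular distance
#'   in scaled space; 0 for 1-D data) and `flagged`.
#' @examples
#' ep <- twoStateEndpoints(c(c = 13.00), c(c = 14.00))
#' estimatePU(ep, 13.42)$pU  # 0.42
#' @export
estimatePU <- function(endpoints, delta_obs) {
  stopifnot(inherits(endpoints, "twoStateEndpoints"))
  obs <- .asHC(delta_obs)
  use <- !is.na(obs) & !is.na(endpoints$delta_D) & !is.na(endpoints$delta_U)
  if (!any(use)) stop("no nucleus shared between observation and endpoints")
  w_c <- endpoints$w_c
  d0 <- .scaleHC(endpoints$delta_D[use], w_c)
  d1 <- .scaleHC(endpoints$delta_U[use], w_c)
  p <- .scaleHC(obs[use], w_c)
  seg <- d1 - d0
  len2 <- sum(seg^2)
  if (len2 == 0) stop("degenerate endpoints for this observation")
  pU <- sum((p - d0) * seg) / len2
  perp <- sqrt(max(sum((p - d0 - pU * seg)^2), 0))
  flagged <- pU < -0.05 || pU > 1.05
  list(pU = pU, pD = 1 - pU, deviation_ppm = perp, flagged = flagged)
}

#' Aggregate per-reporter population estimates
#'
#' Unweighted mean and sample SD across reporters; outlier-flagged
#' estimates (pU outside \[-0.05, 1.05\]) are excluded from the summary
#' by default and listed.
#'
#' @param estimates list of results from [estimatePU()], or a bare
#'   numeric vector of pU values.
#' @param drop_flagged exclude flagged estimates from the summary.
#' @return list with `mean`, `sd` (NA for a single estimate), `n`,
#'   `table` (per-reporter data.frame) and `excluded` (indices/names).
#' @examples
#' aggregatePU(c(I189 = 0.14, L229 = 0.13, M388 = 0.13))
#' @export
aggregatePU <- function(estimates, drop_flagged = TRUE) {
  if (is.numeric(estimates))
    estimates <- lapply(estimates, function(p)
      list(pU = p, deviation_ppm = NA_real_,
           flagged = p < -0.05 || p > 1.05))
  if (!length(estimates)) stop("no estimates supplied")
  tab <- data.frame(
    reporter = if (is.null(names(estimates)))
      seq_along(estimates) else names(estimates),
    pU = vapply(estimates, `[[`, 0, "pU"),
    deviation_ppm = vapply(estimates, `[[`, 0, "deviation_ppm"),
    flagged = vapply(estimates, `[[`, TRUE, "flagged"),
    stringsAsFactors = FALSE)
  keep <- if (drop_flagged) !tab$flagged else rep(TRUE, nrow(tab))
  if (!any(keep)) stop("all estimates flagged as outliers")
  p <- tab$pU[keep]
  list(mean = mean(p),
       sd = if (length(p) > 1) stats::sd(p) else NA_real_,
       n = length(p), table = tab,
       excluded = tab$reporter[!keep])
}

#' Linearity of a shift trajectory across a mutant series
#'
#' Shifts that titrate between two states in fast exchange must move
#' along the straight D-to-U segment; curvature signals a third state or
#' site-specific structural perturbation.  Reports the perpendicular
#' deviation of every variant from the segment (scaled 2-D space) and
#' flags the trajectory when any deviation exceeds the threshold.
#'
#' @param trajectory data.frame with columns `variant`, `delta_h_ppm`,
#'   `delta_c_ppm` (one row per variant) for a single reporter.
#' @param endpoints a [twoStateEndpoints()].
#' @param threshold flag threshold on the perpendicular deviation, ppm.
#' @return data.frame per variant with `pU`, `deviation_ppm`, `flagged`,
#'   plus attribute `monotonic` (TRUE when the fitted pU are ordered as
#'   given).
#' @export
collinearity <- function(trajectory, endpoints, threshold = 0.02) {
  if (nrow(trajectory) < 3)
    stop("need at least 3 variants to assess collinearity")
  res <- lapply(seq_len(nrow(trajectory)), function(i) {
    est <- estimatePU(endpoints,
                      c(h = trajectory$delta_h_ppm[i],
                        c = trajectory$delta_c_ppm[i]))
    data.frame(variant = trajectory$variant[i], pU = est$pU,
               deviation_ppm = est$deviation_ppm,
               flagged = est$deviation_ppm > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "monotonic") <- !is.unsorted(out$pU) ||
    !is.unsorted(rev(out$pU))
  out
}

#' Free-energy difference of the up/down equilibrium
#'
#' \eqn{\Delta G_{up/down} = RT \ln((1-p_U)/p_U)} in cal/mol with
#' R = 1.9872 cal mol^-1 K^-1; positive when the down state is favoured,
#' zero at pU = 0.5 and antisymmetric under pU -> 1 - pU.
#'
#' @param pU up-state fraction, strictly inside (0, 1).  Vectorized.
#' @param temperature K, default 323.15 (50 C experiments).
#' @return Delta G in cal/mol.
#' @examples
#' deltaG(0.14)  # ~1166 cal/mol
#' deltaG(0.42)  # ~207 cal/mol
#' @export
deltaG <- function(pU, temperature = 323.15) {
  if (any(!is.finite(pU)) || any(pU <= 0) || any(pU >= 1))
    stop("pU must lie strictly between 0 and 1 (Delta G diverges at 0/1)")
  .R_CAL * temperature * log((1 - pU) / pU)
}

#' Lower bound on the exchange rate from fast-exchange shift differences
#'
#' A single population-averaged peak requires exchange faster than the
#' angular shift difference between the exchanging states,
#' \eqn{k_{ex} \gtrsim \Delta\omega = 2\pi\,\Delta\delta\,\nu_0}, with
#' \eqn{\nu_0} the nucleus resonance frequency (13C at 0.25145 times the
#' 1H field).  Returns the larger bound over the supplied nuclei.
#'
#' @param d_delta_h,d_delta_c absolute shift differences, ppm (either may
#'   be 0 or NA to skip that nucleus).
#' @param field_h_mhz 1H spectrometer frequency, MHz.
#' @return minimum exchange rate, s^-1 (rad/s).
#' @examples
#' exchangeBound(d_delta_h = 0, d_delta_c = 1.0, field_h_mhz = 800)
#' @export
exchangeBound <- function(d_delta_h = 0, d_delta_c = 0, field_h_mhz) {
  if (field_h_mhz <= 0) stop("field must be positive")
  dh <- abs(ifelse(is.na(d_delta_h), 0, d_delta_h))
  dc <- abs(ifelse(is.na(d_delta_c), 0, d_delta_c))
  if (dh == 0 && dc == 0)
    stop("undefined bound: both shift differences are zero")
  max(2 * pi * dh * field_h_mhz,
      2 * pi * dc * field_h_mhz * .NU_RATIO_C13)
}

#' Chemical shift perturbations between two shift tables
#'
#' Inner-joins two tables on (residue, atom) and computes per-reporter
#' 1H and 13C differences plus the combined perturbation
#' \eqn{\sqrt{\Delta\delta_H^2 + (w_C\,\Delta\delta_C)^2}}.  Reporters
#' present in only one table are listed in the `unmatched` attribute, not
#' silently dropped.
#'
#' @param state_a,state_b data.frames with columns `residue`, `atom`,
#'   `delta_h_ppm`, `delta_c_ppm`.
#' @param w_c carbon weight (default 0.25).
#' @return data.frame with `residue`, `atom`, `d_delta_h`, `d_delta_c`,
#'   `combined` (ppm, b minus a per nucleus).
#' @export
cspTable <- function(state_a, state_b, w_c = 0.25) {
  key <- function(d) paste(d$residue, d$atom, sep = "|")
  ka <- key(state_a); kb <- key(state_b)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no reporters shared between the two tables")
  ia <- match(common, ka); ib <- match(common, kb)
  dh <- state_b$delta_h_ppm[ib] - state_a$delta_h_ppm[ia]
  dc <- state_b$delta_c_ppm[ib] - state_a$delta_c_ppm[ia]
  out <- data.frame(
    residue = state_a$residue[ia], atom = state_a$atom[ia],
    d_delta_h = dh, d_delta_c = dc,
    combined = sqrt(ifelse(is.na(dh), 0, dh)^2 +
                    (w_c * ifelse(is.na(dc), 0, dc))^2),
    stringsAsFactors = FALSE)
  attr(out, "unmatched") <- c(setdiff(ka, kb), setdiff(kb, ka))
  out
}

#' Default p97 domain boundaries (Uniprot P55072 numbering)
#'
#' @return named list of residue ranges for domain annotation.
#' @export
p97Domains <- function() {
  list(NTD = c(1, 187), linker = c(188, 208), D1 = c(209, 480))
}

#' Residues with perturbations above a threshold
#'
#' Filters a CSP table to reporters whose combined perturbation strictly
#' exceeds the threshold and annotates each with its domain.
#'
#' @param records data.frame from [cspTable()].
#' @param threshold ppm, strict (default 0.3).
#' @param domains named list of residue ranges, as [p97Domains()].
#' @return data.frame (residue, atom, combined, domain), sorted by
#'   residue; zero rows when nothing exceeds the threshold.
#' @export
classifyCsp <- function(records, threshold = 0.3, domains = p97Domains()) {
  stopifnot(threshold > 0)
  hit <- records[records$combined > threshold, , drop = FALSE]
  dom <- vapply(hit$residue, function(r) {
    m <- names(domains)[vapply(domains, function(rg)
      r >= rg[1] && r <= rg[2], TRUE)]
    if (length(m)) m[1] else NA_character_
  }, "")
  out <- data.frame(residue = hit$residue, atom = hit$atom,
                    combined = hit$combined, domain = dom,
                    stringsAsFactors = FALSE)
  out[order(out$residue), , drop = FALSE]
}
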