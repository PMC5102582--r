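#' Fraction bound from a population-averaged chemical shift
#'
#' Under fast exchange the observed shift is the population-weighted mean
#' of free- and bound-state shifts, so
#' \eqn{f_B = (\delta_i - \delta_F)/(\delta_B - \delta_F)}.
#' With paired 1H/13C shifts (length-2 vectors, carbon second) the point
#' is projected orthogonally onto the free-to-bound segment in scaled 2-D
#' shift space, which reduces to 1-D interpolation when one nucleus
#' dominates.
#'
#' @param delta_i observed shift(s), ppm (scalar, or c(H, C)).
#' @param delta_F free-state shift(s), ppm.
#' @param delta_B bound-state shift(s), ppm.
#' @param w_c carbon weight for the 2-D scaled space.
#' @return fB, with attribute `flagged` set to TRUE when fB falls outside
#'   \[-0.05, 1.05\] (a warning is raised; the value is not clamped).
#' @examples
#' fractionBound(0.54, 0.50, 0.60)  # 0.4
#' @export
fractionBound <- function(delta_i, delta_F, delta_B, w_c = 0.25) {
  n <- length(delta_i)
  stopifnot(length(delta_F) == n, length(delta_B) == n, n %in% c(1L, 2L))
  w <- if (n == 2L) c(1, w_c) else 1
  d <- (delta_B - delta_F) * w
  if (sum(d^2) == 0)
    stop("degenerate endpoints: delta_B equals delta_F")
  fB <- sum(((delta_i - delta_F) * w) * d) / sum(d^2)
  flagged <- fB < -0.05 || fB > 1.05
  if (flagged)
    warning(sprintf("fraction bound %.3f outside [-0.05, 1.05]", fB))
  structure(fB, flagged = flagged)
}

#' Single-point microscopic Kd with ligand depletion
#'
#' From one measured fraction bound at known totals: with
#' bound = fB * PT_sites,
#' Kd = (PT_sites - bound)(LT - bound)/bound.
#'
#' @param fB fraction of sites bound, in (0, 1).
#' @param PT_sites total binding-site concentration, uM.
#' @param LT total ligand concentration, uM.
#' @return Kd in uM.
#' @examples
#' kdSingleSite(fB = 0.4, PT_sites = 50, LT = 150)  # 195 uM
#' @export
kdSingleSite <- function(fB, PT_sites, LT) {
  if (!is.finite(fB) || fB <= 0 || fB >= 1)
    stop("fB must lie strictly between 0 and 1")
  if (PT_sites <= 0 || LT <= 0) stop("PT_sites and LT must be positive")
  bound <- fB * PT_sites
  if (bound >= LT)
    stop("infeasible occupancy: fB * PT_sites must be below LT")
  (PT_sites - bound) * (LT - bound) / bound
}

#' Exact single-site ligand-depletion isotherm
#'
#' Fraction of protein sites bound at total concentrations PT and LT for
#' dissociation constant Kd:
#' \deqn{f_B = \frac{P_T + L_T + K_d - \sqrt{(P_T+L_T+K_d)^2 - 4P_TL_T}}
#'   {2P_T}.}
#' At Kd = 0 this reduces to stoichiometric binding min(1, LT/PT).
#'
#' @param PT,LT totals, uM.  `LT` may be a vector.
#' @param kd dissociation constant, uM (>= 0).
#' @return fB, same length as LT.
#' @export
fbDepletion <- function(PT, LT, kd) {
  stopifnot(PT > 0, all(LT >= 0), kd >= 0)
  s <- PT + LT + kd
  (s - sqrt(pmax(s^2 - 4 * PT * LT, 0))) / (2 * PT)
}

#' Build a titration series from a long-format table
#'
#' @param data data.frame with columns `reporter`, `ligand_total_uM` and
#'   at least one of `delta_h_ppm` / `delta_c_ppm`; optional `sigma_ppm`.
#' @param PT fixed total protomer concentration, uM.
#' @return list of class `titrationSeries` with `data` and `PT`.
#' @export
titrationSeries <- function(data, PT) {
  need <- c("reporter", "ligand_total_uM")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("titration table lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(c("delta_h_ppm", "delta_c_ppm") %in% names(data)))
    stop("titration table needs delta_h_ppm and/or delta_c_ppm")
  if (any(data$ligand_total_uM < 0)) stop("ligand totals must be >= 0")
  for (r in unique(data$reporter)) {
    lt <- sort(unique(data$ligand_total_uM[data$reporter == r]))
    if (length(lt) < 2)
      stop("reporter ", r, " has fewer than 2 titration points")
    if (!any(lt == 0))
      stop("reporter ", r, " lacks a zero-ligand (free state) point")
  }
  structure(list(data = data, PT = PT), class = "titrationSeries")
}

# one response channel per reporter x nucleus, free shift fixed at LT = 0
.titrationChannels <- function(series) {
  d <- series$data
  nuclei <- intersect(c("delta_h_ppm", "delta_c_ppm"), names(d))
  out <- list()
  for (r in unique(d$reporter)) {
    sub <- d[d$reporter == r, , drop = FALSE]
    sub <- sub[order(sub$ligand_total_uM), , drop = FALSE]
    for (nuc in nuclei) {
      y <- sub[[nuc]]
      if (all(is.na(y))) next
      sig_col <- if (nuc == "delta_h_ppm") "sigma_h_ppm" else "sigma_c_ppm"
      sigma <- if (sig_col %in% names(sub)) sub[[sig_col]] else
        if ("sigma_ppm" %in% names(sub)) sub$sigma_ppm else
          rep(1, nrow(sub))
      dF <- y[sub$ligand_total_uM == 0][1]
      out[[paste(r, nuc, sep = ".")]] <- list(
        reporter = r, nucleus = nuc, LT = sub$ligand_total_uM,
        y = y, sigma = ifelse(is.finite(sigma) & sigma > 0, sigma, 1),
        deltaF = dF)
    }
  }
  if (!length(out)) stop("no usable titration channels")
  out
}

# weighted chi^2 at fixed kd, profiling out the per-channel bound shifts
.titrationChisq <- function(kd, channels, PT) {
  total <- 0
  for (ch in channels) {
    fb <- fbDepletion(PT, ch$LT, kd)
    w <- 1 / ch$sigma^2
    num <- sum(w * fb * (ch$y - ch$deltaF))
    den <- sum(w * fb^2)
    amp <- if (den > 0) num / den else 0
    total <- total + sum(w * (ch$y - ch$deltaF - amp * fb)^2)
  }
  total
}

#' Global fit of a macroscopic Kd to chemical-shift titration profiles
#'
#' Fits one shared dissociation constant to all reporters (and nuclei)
#' simultaneously using the exact ligand-depletion isotherm
#' [fbDepletion()].  The free-state shift of each channel is fixed at its
#' measured zero-ligand value; the bound-state shift of each channel is a
#' linear amplitude profiled out analytically at each trial Kd, so the
#' optimization is one-dimensional and convergence is robust.  The
#' standard error comes from the curvature of the chi-square profile.
#'
#' @param series a [titrationSeries()].
#' @param kd_range search interval for Kd, uM.
#' @return a [KdMacroFit-class] object.
#' @export
fitTitration <- function(series, kd_range = c(1e-3, 1e5)) {
  stopifnot(inherits(series, "titrationSeries"))
  channels <- .titrationChannels(series)
  npar <- 1L + length(channels)
  nobs <- sum(vapply(channels, function(ch) sum(ch$LT > 0), 0L))
  if (nobs < npar)
    stop("unidentifiable fit: ", nobs, " informative shifts for ",
         npar, " parameters")
  PT <- series$PT
  # log-grid scan guards against local minima, then golden-section refine
  grid <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = 120))
  chi <- vapply(grid, .titrationChisq, 0, channels = channels, PT = PT)
  i <- which.min(chi)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(.titrationChisq, c(lo, hi), channels = channels,
                         PT = PT, tol = 1e-10 * grid[i])
  kd <- opt$minimum
  # SE from the numerical second derivative of chi^2: var = 2/chi''
  h <- max(1e-4 * kd, 1e-8)
  d2 <- (.titrationChisq(kd + h, channels, PT) - 2 * opt$objective +
         .titrationChisq(kd - h, channels, PT)) / h^2
  dof <- max(nobs - npar, 1L)
  scale <- max(opt$objective / dof, .Machine$double.eps)
  se <- if (d2 > 0) sqrt(2 * scale / d2) else NA_real_
  deltaB <- do.call(rbind, lapply(names(channels), function(nm) {
    ch <- channels[[nm]]
    fb <- fbDepletion(PT, ch$LT, kd)
    w <- 1 / ch$sigma^2
    amp <- sum(w * fb * (ch$y - ch$deltaF)) / sum(w * fb^2)
    data.frame(channel = nm, reporter = ch$reporter, nucleus = ch$nucleus,
               delta_F_ppm = ch$deltaF, delta_B_ppm = ch$deltaF + amp,
               stringsAsFactors = FALSE)
  }))
  new("KdMacroFit", kd = kd, se = se, deltaB = deltaB,
      chisq = opt$objective, nobs = as.integer(nobs), PT = PT)
}
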