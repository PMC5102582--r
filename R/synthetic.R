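#' Reporter model for the synthetic-shift generator
#'
#' Describes one methyl probe: its limiting shifts in the down (D) and up
#' (U) NTD states, and optionally distinct shifts for the locked-down
#' state and for the VIM-bound state.
#'
#' @param id reporter label, e.g. "I189".
#' @param residue 1-based residue number (Uniprot P55072 numbering).
#' @param atom methyl label, one of ILE-CD1, LEU-CD-proR, VAL-CG-proR,
#'   MET-CE.
#' @param class one of `"equilibrium"` (responds to the up/down/locked
#'   populations), `"vim_site"` (responds to VIM-site occupancy) or
#'   `"locked_sensitive"` (equilibrium probe whose locked-state shift
#'   differs from the plain down state).
#' @param delta_D,delta_U named `c(h = , c = )` shifts, ppm.
#' @param delta_lock locked-state shifts; defaults to `delta_D` (only
#'   some probes resolve locking).
#' @param delta_vim VIM-bound shifts (required for class `"vim_site"`).
#' @return list of class `reporterModel`.
#' @export
reporterModel <- function(id, residue, atom, class = c("equilibrium",
                          "vim_site", "locked_sensitive"),
                          delta_D, delta_U, delta_lock = NULL,
                          delta_vim = NULL) {
  class <- match.arg(class)
  if (class == "vim_site" && is.null(delta_vim))
    stop("vim_site reporter ", id, " requires delta_vim endpoint shifts")
  if (is.null(delta_lock)) delta_lock <- delta_D
  structure(list(id = id, residue = residue, atom = atom, class = class,
                 delta_D = delta_D, delta_U = delta_U,
                 delta_lock = delta_lock, delta_vim = delta_vim),
            class = "reporterModel")
}

#' Default synthetic reporter set
#'
#' Emulates the probes used throughout the analysis: I189, L229 and M388
#' as large-CSP up/down equilibrium reporters (I189 with the largest 13C
#' separation), I146 as a locked-state-sensitive equilibrium probe and
#' V68 as a VIM-site binding proxy.  Endpoint shifts are synthetic
#' fixture values with realistic methyl shift ranges and CSP magnitudes;
#' they are not published assignments.
#'
#' @return named list of [reporterModel()] objects.
#' @export
defaultReporterModels <- function() {
  list(
    I189 = reporterModel("I189", 189, "ILE-CD1", "equilibrium",
                         delta_D = c(h = 0.75, c = 13.00),
                         delta_U = c(h = 0.55, c = 14.00)),
    L229 = reporterModel("L229", 229, "LEU-CD-proR", "equilibrium",
                         delta_D = c(h = 0.82, c = 24.40),
                         delta_U = c(h = 0.70, c = 23.75)),
    M388 = reporterModel("M388", 388, "MET-CE", "equilibrium",
                         delta_D = c(h = 1.95, c = 17.10),
                         delta_U = c(h = 2.12, c = 16.55)),
    I146 = reporterModel("I146", 146, "ILE-CD1", "locked_sensitive",
                         delta_D = c(h = 0.60, c = 11.20),
                         delta_U = c(h = 0.49, c = 11.60),
                         delta_lock = c(h = 0.64, c = 11.05)),
    V68 = reporterModel("V68", 68, "VAL-CG-proR", "vim_site",
                        delta_D = c(h = 0.85, c = 21.50),
                        delta_U = c(h = 0.85, c = 21.50),
                        delta_vim = c(h = 0.97, c = 21.95)),
    V108 = reporterModel("V108", 108, "VAL-CG-proR", "vim_site",
                         delta_D = c(h = 0.78, c = 20.90),
                         delta_U = c(h = 0.78, c = 20.90),
                         delta_vim = c(h = 0.70, c = 21.20)),
    I175 = reporterModel("I175", 175, "ILE-CD1", "vim_site",
                         delta_D = c(h = 0.66, c = 12.40),
                         delta_U = c(h = 0.66, c = 12.40),
                         delta_vim = c(h = 0.74, c = 12.10))
  )
}

#' Default variant series with generating up-state fractions
#'
#' The mutant severity series used as generating truth: wt-ADP fully
#' down, R155H / L198W / R191Q / R95G progressively more up (I189-derived
#' fractions 0.14, 0.27, 0.39, 0.42), and the ATPgS state fully up.
#'
#' @return named numeric of pU per variant.
#' @export
defaultVariants <- function() {
  c(wt = 0, R155H = 0.14, L198W = 0.27, R191Q = 0.39, R95G = 0.42,
    ATPgS = 1.0)
}

#' Default noise standard deviations for all generators
#'
#' @return list: `shift_h`, `shift_c` (ppm), `ratio` (absolute),
#'   `rate_frac` (fractional, on 15N rates).
#' @export
defaultNoise <- function() {
  list(shift_h = 0.002, shift_c = 0.01, ratio = 0.01, rate_frac = 0.02)
}

#' Generate a two-state shift table across a variant series
#'
#' Forward model of fast-exchange averaging: for each reporter and
#' variant, \eqn{\delta = p_D\delta_D + p_U\delta_U} per nucleus, plus
#' optional Gaussian noise.  A third weight for the locked-down state can
#' be supplied per variant, mixing in each reporter's `delta_lock`.
#'
#' @param reporters list of [reporterModel()] (default
#'   [defaultReporterModels()]).
#' @param variants named numeric of generating pU values (default
#'   [defaultVariants()]).
#' @param p_lock optional named numeric of locked-state weights per
#'   variant (taken out of the down population).
#' @param noise list as [defaultNoise()], or NULL for noise-free output.
#' @param seed integer; mandatory when `noise` is non-NULL.
#' @param state nucleotide-state label written to the table.
#' @return data.frame in the `shifts.csv` schema: `variant`, `state`,
#'   `residue`, `atom`, `delta_h_ppm`, `delta_c_ppm`.
#' @examples
#' head(genShiftSeries(noise = NULL))
#' @export
genShiftSeries <- function(reporters = defaultReporterModels(),
                           variants = defaultVariants(), p_lock = NULL,
                           noise = NULL, seed = NULL, state = "ADP") {
  if (any(variants < 0 | variants > 1))
    stop("generating pU values must lie in [0, 1]")
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is mandatory for noisy output")
    set.seed(seed)
  }
  rows <- list()
  for (rp in reporters) {
    for (v in names(variants)) {
      pU <- variants[[v]]
      pl <- if (!is.null(p_lock) && v %in% names(p_lock)) p_lock[[v]] else 0
      if (pl > 1 - pU + 1e-12)
        stop("locked weight exceeds the down population for ", v)
      d <- pU * rp$delta_U + (1 - pU - pl) * rp$delta_D + pl * rp$delta_lock
      if (!is.null(noise))
        d <- d + c(h = stats::rnorm(1, 0, noise$shift_h),
                   c = stats::rnorm(1, 0, noise$shift_c))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, state = if (v == "ATPgS") "ATPgS" else state,
        residue = rp$residue, atom = rp$atom,
        delta_h_ppm = unname(d["h"]), delta_c_ppm = unname(d["c"]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate methyl triple-quantum buildup curves
#'
#' Forward model: eta from [etaFromTau()] per methyl, ratios from
#' [tqRatio()] on the requested delay grid, plus additive Gaussian noise.
#'
#' @param methyls data.frame with columns `reporter`, `s2_axis`,
#'   `tau_c_ns`, `delta_density` (s^-1).
#' @param delays s (default the 0.5-18 ms grid).
#' @param noise_sd absolute SD on the ratio, or 0 for noise-free.
#' @param seed integer; mandatory when `noise_sd > 0`.
#' @return data.frame in the `buildup.csv` schema: `reporter`, `delay_s`,
#'   `ratio`, `sigma`.
#' @export
genBuildup <- function(methyls, delays = buildupDelays("nd1l"),
                       noise_sd = 0, seed = NULL) {
  stopifnot(all(c("reporter", "s2_axis", "tau_c_ns", "delta_density")
                %in% names(methyls)))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is mandatory for noisy output")
    set.seed(seed)
  }
  rows <- lapply(seq_len(nrow(methyls)), function(i) {
    m <- methyls[i, ]
    r <- tqRatio(etaFromTau(m$s2_axis, m$tau_c_ns), m$delta_density, delays)
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
    data.frame(reporter = m$reporter, delay_s = delays, ratio = r,
               sigma = if (noise_sd > 0) noise_sd else 1e-6,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a 15N relaxation table from model-free parameters
#'
#' Forward-computes R1, R2 and NOE per residue from [n15Rates()] with the
#' same interaction constants the mapping assumes, re-expresses R2 as
#' R1rho through the tilt-angle relation at the given spin-lock and
#' offset, and applies multiplicative Gaussian noise to the rates.
#'
#' @param params data.frame with columns `residue`, `tau_c_ns`, `s2`,
#'   `tau_e_ps`.
#' @param field_h_mhz 1H frequency, MHz (default 600).
#' @param nu1_hz spin-lock field, Hz (default 1800).
#' @param offset_hz per-residue offsets from the carrier (recycled).
#' @param noise_frac fractional rate noise, or 0 for noise-free.
#' @param seed integer; mandatory when `noise_frac > 0`.
#' @return data.frame in the `relax15n.csv` schema.
#' @export
genN15 <- function(params, field_h_mhz = 600, nu1_hz = 1800,
                   offset_hz = 0, noise_frac = 0, seed = NULL) {
  stopifnot(all(c("residue", "tau_c_ns", "s2", "tau_e_ps")
                %in% names(params)))
  if (noise_frac > 0) {
    if (is.null(seed)) stop("a seed is mandatory for noisy output")
    set.seed(seed)
  }
  offset_hz <- rep_len(offset_hz, nrow(params))
  rows <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    rates <- n15Rates(p$tau_c_ns, p$s2, p$tau_e_ps, field_h_mhz)
    theta <- atan2(nu1_hz, offset_hz[i])
    r1rho <- rates["r2"] * sin(theta)^2 + rates["r1"] * cos(theta)^2
    out <- c(r1 = unname(rates["r1"]), r1rho = unname(r1rho),
             noe = unname(rates["noe"]))
    if (noise_frac > 0) {
      out["r1"] <- out["r1"] * (1 + stats::rnorm(1, 0, noise_frac))
      out["r1rho"] <- out["r1rho"] * (1 + stats::rnorm(1, 0, noise_frac))
      out["noe"] <- out["noe"] + stats::rnorm(1, 0, noise_frac *
                                              abs(1 - out["noe"]))
    }
    data.frame(residue = p$residue, r1 = out["r1"],
               r1_err = noise_frac * out["r1"],
               r1rho = out["r1rho"], r1rho_err = noise_frac * out["r1rho"],
               noe = out["noe"], noe_err = noise_frac,
               field_h_mhz = field_h_mhz, nu1_hz = nu1_hz,
               offset_hz = offset_hz[i], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate an adaptor titration from the six-state scheme
#'
#' For each total-ligand point the full speciation is solved, and each
#' reporter's shift follows its class: VIM-site probes move toward their
#' bound-state shift in proportion to the VIM-site occupancy
#' (UV + DV + DHV)/PT; equilibrium probes average over the apparent up,
#' free-down and locked (DH + DHV) populations using their `delta_lock`
#' endpoint for the locked states.
#'
#' @param scheme a [SchemeOneParams-class].
#' @param PT total protomer, uM.
#' @param LT_grid total-ligand grid, uM (must include 0 for the free
#'   state).
#' @param reporters list of [reporterModel()].
#' @param noise list as [defaultNoise()], or NULL for noise-free.
#' @param seed integer; mandatory when `noise` is non-NULL.
#' @return data.frame in the `titration.csv` schema: `reporter`,
#'   `residue`, `atom`, `protein_total_uM`, `ligand_total_uM`,
#'   `delta_h_ppm`, `delta_c_ppm`, `sigma_h_ppm`, `sigma_c_ppm`.
#' @export
genTitration <- function(scheme, PT = 50,
                         LT_grid = c(0, 12.5, 25, 50, 100, 150, 250),
                         reporters = defaultReporterModels(),
                         noise = NULL, seed = NULL) {
  stopifnot(is(scheme, "SchemeOneParams"))
  if (!any(LT_grid == 0)) stop("LT grid must include the zero-ligand point")
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is mandatory for noisy output")
    set.seed(seed)
  }
  rows <- list()
  for (LT in sort(LT_grid)) {
    sp <- speciate(scheme, mixtureTotals(PT, LT))
    f_vim <- fVimBound(sp)
    p_up <- pUApparent(sp)
    p_lock <- (sp@DH + sp@DHV) / PT
    p_down <- 1 - p_up - p_lock
    for (rp in reporters) {
      d <- if (rp$class == "vim_site") {
        rp$delta_D + f_vim * (rp$delta_vim - rp$delta_D)
      } else {
        p_up * rp$delta_U + p_down * rp$delta_D + p_lock * rp$delta_lock
      }
      if (!is.null(noise))
        d <- d + c(h = stats::rnorm(1, 0, noise$shift_h),
                   c = stats::rnorm(1, 0, noise$shift_c))
      rows[[length(rows) + 1L]] <- data.frame(
        reporter = rp$id, residue = rp$residue, atom = rp$atom,
        protein_total_uM = PT, ligand_total_uM = LT,
        delta_h_ppm = unname(d["h"]), delta_c_ppm = unname(d["c"]),
        sigma_h_ppm = if (is.null(noise)) 1e-6 else noise$shift_h,
        sigma_c_ppm = if (is.null(noise)) 1e-6 else noise$shift_c,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
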