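#' @import methods
NULL

.relDiff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, 0, d / s)
}

#' Equilibrium constants of the six-state NTD/adaptor binding scheme
#'
#' Parameterizes the coupled conformational-selection and two-pronged
#' binding equilibrium of the p97 N-terminal domain (NTD) with an adaptor
#' carrying a VIM motif and an H1/H2 motif.  The six species are U and D
#' (NTD up/down, adaptor-free), UV and DV (VIM-bound), DH (H1/H2-bound,
#' down only) and DHV (doubly bound, "locked down").
#'
#' Constants follow the defining ratios
#' K1 = [U]/[D] = [UV]/[DV] (dimensionless),
#' K2 = [U][L]/[UV] = [D][L]/[DV] (microscopic VIM dissociation constant,
#' uM), K3 = [D][L]/[DH] (microscopic H1/H2 dissociation constant, uM),
#' K4 = [DH]/[DHV] and K5 = [DV]/[DHV] (dimensionless intramolecular
#' constants), with the thermodynamic-cycle closure
#' K4/K5 = K2/K3 = 1/gamma.
#'
#' @slot K1,K2,K3,K4,K5,gamma numeric(1), see above.  All strictly
#'   positive; K3 = gamma*K2 and K4 = K5/gamma are enforced by validity.
#' @slot temperature numeric(1), annotation only (K), default 323.15.
#' @seealso [deriveScheme()] for the constructor.
#' @export
setClass("SchemeOneParams",
  representation(
    K1 = "numeric", K2 = "numeric", K3 = "numeric",
    K4 = "numeric", K5 = "numeric", gamma = "numeric",
    temperature = "numeric"
  )
)

setValidity("SchemeOneParams", function(object) {
  vals <- c(K1 = object@K1, K2 = object@K2, K3 = object@K3,
            K4 = object@K4, K5 = object@K5, gamma = object@gamma)
  if (any(lengths(lapply(vals, identity)) != 1) || any(!is.finite(vals)))
    return("all equilibrium constants must be finite scalars")
  if (any(vals <= 0))
    return(paste0("non-positive constant: ",
                  paste(names(vals)[vals <= 0], collapse = ", ")))
  if (.relDiff(object@K3, object@gamma * object@K2) > 1e-12)
    return("K3 must equal gamma * K2")
  if (.relDiff(object@K4, object@K5 / object@gamma) > 1e-12)
    return("K4 must equal K5 / gamma")
  TRUE
})

setMethod("show", "SchemeOneParams", function(object) {
  cat("Six-state NTD/adaptor binding scheme\n")
  cat(sprintf("  K1 (up/down)        : %.4g\n", object@K1))
  cat(sprintf("  K2 (VIM Kd, uM)     : %.4g\n", object@K2))
  cat(sprintf("  K3 (H1/H2 Kd, uM)   : %.4g\n", object@K3))
  cat(sprintf("  K4, K5 (locking)    : %.4g, %.4g\n", object@K4, object@K5))
  cat(sprintf("  gamma = K3/K2       : %.4g\n", object@gamma))
  cat(sprintf("  temperature (K)     : %.2f\n", object@temperature))
})

#' Equilibrium speciation of the six-state binding scheme
#'
#' Concentrations (uM) of the six protomer species and free ligand at
#' given totals, as returned by [speciate()].
#'
#' @slot U,D,UV,DV,DH,DHV numeric(1) species concentrations, uM.
#' @slot L numeric(1) free ligand, uM.
#' @slot PT,LT numeric(1) total protomer and ligand, uM.
#' @seealso [speciate()], [pUApparent()], [fLocked()], [fVimBound()]
#' @export
setClass("Speciation",
  representation(
    U = "numeric", D = "numeric", UV = "numeric", DV = "numeric",
    DH = "numeric", DHV = "numeric", L = "numeric",
    PT = "numeric", LT = "numeric"
  )
)

setValidity("Speciation", function(object) {
  conc <- c(object@U, object@D, object@UV, object@DV, object@DH,
            object@DHV, object@L)
  if (any(!is.finite(conc)) || any(conc < -1e-9 * max(object@PT, object@LT, 1)))
    return("species concentrations must be finite and non-negative")
  if (object@PT > 0 &&
      .relDiff(object@U + object@D + object@UV + object@DV + object@DH +
               object@DHV, object@PT) > 1e-9)
    return("protein mass balance violated")
  if (object@LT > 0 &&
      .relDiff(object@L + object@UV + object@DV + object@DH + object@DHV,
               object@LT) > 1e-9)
    return("ligand mass balance violated")
  TRUE
})

setMethod("show", "Speciation", function(object) {
  cat(sprintf("Speciation at PT = %.4g uM, LT = %.4g uM\n",
              object@PT, object@LT))
  print(round(species(object), 4))
  cat(sprintf("  free ligand   : %.4g uM\n", object@L))
  cat(sprintf("  pU (apparent) : %.4f\n", pUApparent(object)))
  cat(sprintf("  f(locked DHV) : %.4f\n", fLocked(object)))
  cat(sprintf("  f(VIM bound)  : %.4f\n", fVimBound(object)))
})

#' @describeIn Speciation named vector of the six species concentrations
#'   (uM).
#' @param object a `Speciation`.
#' @export
species <- function(object) {
  stopifnot(is(object, "Speciation"))
  c(U = object@U, D = object@D, UV = object@UV, DV = object@DV,
    DH = object@DH, DHV = object@DHV)
}

#' @describeIn Speciation free ligand concentration (uM).
#' @export
freeLigand <- function(object) {
  stopifnot(is(object, "Speciation"))
  object@L
}

#' @describeIn Speciation apparent up fraction (U + UV)/PT.
#' @export
pUApparent <- function(object) {
  stopifnot(is(object, "Speciation"))
  (object@U + object@UV) / object@PT
}

#' @describeIn Speciation fraction of protomer in the doubly-bound locked
#'   state, DHV/PT.
#' @export
fLocked <- function(object) {
  stopifnot(is(object, "Speciation"))
  object@DHV / object@PT
}

#' @describeIn Speciation fraction of protomer with the VIM site occupied,
#'   (UV + DV + DHV)/PT.
#' @export
fVimBound <- function(object) {
  stopifnot(is(object, "Speciation"))
  (object@UV + object@DV + object@DHV) / object@PT
}

#' Fit of a methyl 1H triple-quantum buildup curve
#'
#' Result of [fitBuildup()]: the cross-correlated relaxation rate
#' `eta` (s^-1, proportional to \eqn{S^2_{axis}\tau_c}) and the
#' proton-density nuisance parameter `deltaDensity` (s^-1).
#'
#' @slot eta,deltaDensity numeric(1), s^-1.
#' @slot cov 2x2 covariance matrix of (eta, deltaDensity).
#' @slot chisq numeric(1) weighted residual sum of squares.
#' @slot nobs integer(1) number of delay points.
#' @export
setClass("BuildupFit",
  representation(eta = "numeric", deltaDensity = "numeric",
                 cov = "matrix", chisq = "numeric", nobs = "integer")
)

setValidity("BuildupFit", function(object) {
  if (!is.finite(object@eta) || object@eta < 0)
    return("eta must be finite and non-negative")
  TRUE
})

#' @describeIn BuildupFit fitted parameters as a named vector.
#' @param object a `BuildupFit`.
#' @export
setMethod("coef", "BuildupFit", function(object, ...) {
  c(eta = object@eta, delta = object@deltaDensity)
})

#' @describeIn BuildupFit covariance matrix of the fitted parameters.
#' @export
setMethod("vcov", "BuildupFit", function(object, ...) object@cov)

setMethod("show", "BuildupFit", function(object) {
  se <- sqrt(pmax(diag(object@cov), 0))
  cat("Methyl 1H TQ buildup fit\n")
  cat(sprintf("  eta   : %.4g +/- %.3g s^-1\n", object@eta, se[1]))
  cat(sprintf("  delta : %.4g +/- %.3g s^-1\n", object@deltaDensity, se[2]))
  cat(sprintf("  chi^2 : %.4g on %d points\n", object@chisq, object@nobs))
})

#' Global titration fit of a macroscopic dissociation constant
#'
#' Result of [fitTitration()]: one shared macroscopic Kd across all
#' reporters, with per-reporter (per-nucleus) bound-state shifts; the
#' free-state shift of each channel is fixed at its zero-ligand value.
#'
#' @slot kd numeric(1) macroscopic dissociation constant, uM.
#' @slot se numeric(1) standard error of kd, uM.
#' @slot deltaB data.frame of per-channel free and fitted bound-state
#'   shifts (ppm).
#' @slot chisq numeric(1) weighted residual sum of squares.
#' @slot nobs integer(1) number of fitted shift observations.
#' @slot PT numeric(1) total protomer concentration, uM.
#' @export
setClass("KdMacroFit",
  representation(kd = "numeric", se = "numeric", deltaB = "data.frame",
                 chisq = "numeric", nobs = "integer", PT = "numeric")
)

setValidity("KdMacroFit", function(object) {
  if (!is.finite(object@kd) || object@kd <= 0)
    return("kd must be finite and positive")
  TRUE
})

#' @describeIn KdMacroFit the fitted Kd (uM) as a named vector.
#' @param object a `KdMacroFit`.
#' @export
setMethod("coef", "KdMacroFit", function(object, ...) c(kd_uM = object@kd))

setMethod("show", "KdMacroFit", function(object) {
  cat("Global titration fit (shared Kd, ligand-depletion isotherm)\n")
  cat(sprintf("  Kd,macro : %.4g +/- %.3g uM (PT = %.4g uM)\n",
              object@kd, object@se, object@PT))
  cat(sprintf("  chi^2    : %.4g on %d shifts, %d channels\n",
              object@chisq, object@nobs, nrow(object@deltaB)))
})

#' Summary of per-residue rotational correlation times
#'
#' Gaussian (maximum-likelihood) summary of a set of per-residue or
#' per-methyl tau_c estimates, with an optional global weighted fit.
#'
#' @slot values numeric vector of per-residue tau_c, ns.
#' @slot mean,sd numeric(1) ML normal parameters, ns.
#' @slot histogram data.frame with `mid` and `count` columns (reporting
#'   only; the fit is not binned).
#' @export
setClass("TauSummary",
  representation(values = "numeric", mean = "numeric", sd = "numeric",
                 histogram = "data.frame")
)

setMethod("show", "TauSummary", function(object) {
  cat(sprintf("tau_c over %d residues: %.3g +/- %.3g ns (ML Gaussian)\n",
              length(object@values), object@mean, object@sd))
})
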