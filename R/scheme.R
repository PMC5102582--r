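#' Construct the six-state binding scheme from its free constants
#'
#' The scheme has a single thermodynamically independent binding pathway:
#' given K1 (up/down), K2 (microscopic VIM Kd, uM), gamma = K3/K2 and K5,
#' the remaining constants follow from cycle closure as K3 = gamma*K2 and
#' K4 = K5/gamma.
#'
#' @param K1 dimensionless up/down equilibrium constant \[U\]/\[D\].
#' @param K2 microscopic VIM dissociation constant, uM.
#' @param gamma dimensionless ratio K3/K2 = K5/K4.
#' @param K5 dimensionless intramolecular constant \[DV\]/\[DHV\].
#' @param temperature annotation only, K.
#' @return a [SchemeOneParams-class] object.
#' @examples
#' deriveScheme(K1 = 0.15, K2 = 200, gamma = 125, K5 = 0.5)
#' @export
deriveScheme <- function(K1, K2, gamma, K5, temperature = 323.15) {
  args <- c(K1 = K1, K2 = K2, gamma = gamma, K5 = K5)
  bad <- !is.finite(args) | args <= 0
  if (any(bad))
    stop("equilibrium constant must be positive and finite: ",
         paste(names(args)[bad], collapse = ", "))
  new("SchemeOneParams", K1 = K1, K2 = K2, K3 = gamma * K2,
      K4 = K5 / gamma, K5 = K5, gamma = gamma, temperature = temperature)
}

#' Total protomer and ligand concentrations
#'
#' @param PT total NTD protomer concentration, uM.
#' @param LT total ligand (adaptor) concentration, uM.
#' @return list with elements `PT` and `LT`.
#' @export
mixtureTotals <- function(PT, LT) {
  if (!is.finite(PT) || PT < 0) stop("PT must be non-negative and finite")
  if (!is.finite(LT) || LT < 0) stop("LT must be non-negative and finite")
  list(PT = PT, LT = LT)
}

#' Quadratic in the free-ligand concentration
#'
#' Mass balance over the six species reduces to
#' \eqn{A[L]^2 + B[L] + C = 0} with
#' \eqn{A = \alpha\Sigma}, \eqn{\alpha = K_1/(1+K_1)},
#' \eqn{\Sigma = 1/K_2 + 1/(K_1K_2) + 1/(K_1K_3) + 1/(K_1K_3K_4)},
#' \eqn{B = A(P_T - L_T) + 1} and \eqn{C = -L_T}.
#'
#' @param params a [SchemeOneParams-class].
#' @param totals a list from [mixtureTotals()].
#' @return list with `A` (uM^-1), `B`, `C` (uM), `alpha`, `sigma_sum`
#'   (uM^-1) and the totals.
#' @export
ligandQuadratic <- function(params, totals) {
  stopifnot(is(params, "SchemeOneParams"))
  validObject(params)
  K1 <- params@K1; K2 <- params@K2; K3 <- params@K3; K4 <- params@K4
  alpha <- K1 / (1 + K1)
  sigma_sum <- 1 / K2 + 1 / (K1 * K2) + 1 / (K1 * K3) + 1 / (K1 * K3 * K4)
  A <- alpha * sigma_sum
  list(A = A, B = A * (totals$PT - totals$LT) + 1, C = -totals$LT,
       alpha = alpha, sigma_sum = sigma_sum,
       PT = totals$PT, LT = totals$LT)
}

#' Solve for the free-ligand concentration
#'
#' Returns the unique root of the mass-balance quadratic in \[0, LT\],
#' using the numerically stable q-form of the quadratic formula to avoid
#' cancellation when B is close to -sqrt(B^2 - 4AC).
#'
#' @param quad list from [ligandQuadratic()].
#' @return free ligand concentration, uM.
#' @export
solveFreeLigand <- function(quad) {
  A <- quad$A; B <- quad$B; C <- quad$C; LT <- quad$LT
  if (LT == 0) return(0)
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("internal inconsistency: negative discriminant")
  # q-method: q = -(B + sign(B) sqrt(disc)); roots are q/(2A) and 2C/q
  q <- -(B + sign(B) * sqrt(disc))
  roots <- c(q / (2 * A), 2 * C / q)
  tol <- 1e-9 * LT
  ok <- roots >= -tol & roots <= LT + tol
  if (!any(ok)) stop("internal inconsistency: no root in [0, LT]")
  min(max(roots[ok][1], 0), LT)
}

#' Exact speciation of the six-state scheme
#'
#' Solves the free-ligand quadratic and reconstructs all six species from
#' the defining equilibrium ratios.  With bound ligand LT - L, the free
#' protomer pool is U + D = PT - (LT - L), split as U = alpha*(U+D); the
#' bound species follow as UV = U L/K2, DV = D L/K2, DH = D L/K3 and
#' DHV = D L/(K3 K4).
#'
#' @inheritParams ligandQuadratic
#' @return a [Speciation-class] object.
#' @examples
#' sc <- deriveScheme(K1 = 0.15, K2 = 200, gamma = 125, K5 = 0.5)
#' sp <- speciate(sc, mixtureTotals(PT = 50, LT = 150))
#' fLocked(sp)    # ~0.39 of protomer locked down
#' pUApparent(sp) # up fraction pushed to ~0.08
#' @export
speciate <- function(params, totals) {
  quad <- ligandQuadratic(params, totals)
  L <- solveFreeLigand(quad)
  K2 <- params@K2; K3 <- params@K3; K4 <- params@K4
  UD <- totals$PT - (totals$LT - L)
  U <- quad$alpha * UD
  D <- (1 - quad$alpha) * UD
  new("Speciation",
      U = U, D = D, UV = U * L / K2, DV = D * L / K2,
      DH = D * L / K3, DHV = D * L / (K3 * K4), L = L,
      PT = totals$PT, LT = totals$LT)
}

#' Macroscopic dissociation constant of the full scheme
#'
#' The effective Kd reported by VIM-sensitive probes,
#' \deqn{K_{d,macro} = \frac{([D]+[U]+[DH])[L]}{[UV]+[DV]+[DHV]}
#'   = \frac{K_2(1+K_1) + [L]/\gamma}{1 + K_1 + 1/K_5},}
#' evaluated at the free-ligand concentration solved from the totals.
#'
#' @inheritParams ligandQuadratic
#' @return Kd,macro in uM.
#' @export
kdMacro <- function(params, totals) {
  stopifnot(is(params, "SchemeOneParams"))
  if (totals$LT <= 0)
    stop("kdMacro is undefined at LT = 0 (no bound species)")
  L <- solveFreeLigand(ligandQuadratic(params, totals))
  (params@K2 * (1 + params@K1) + L / params@gamma) /
    (1 + params@K1 + 1 / params@K5)
}

#' Asymptotic limits of the macroscopic Kd
#'
#' In the wild-type regime (1/K5 >> 1 + K1 and K1 << 1) the macroscopic
#' Kd reduces to K5*K2; in the severe-mutant regime (1/K5 << 1 + K1 with
#' gamma very large) it reduces to K2.
#'
#' @param params a [SchemeOneParams-class].
#' @param regime `"wt"` or `"severe"`.
#' @return asymptotic Kd,macro in uM.
#' @examples
#' sc <- deriveScheme(K1 = 0.01, K2 = 200, gamma = 25, K5 = 0.1)
#' kdMacroLimit(sc, "wt")      # 20 uM
#' kdMacroLimit(sc, "severe")  # 200 uM
#' @export
kdMacroLimit <- function(params, regime = c("wt", "severe")) {
  stopifnot(is(params, "SchemeOneParams"))
  regime <- match.arg(regime)
  switch(regime,
         wt = params@K5 * params@K2,
         severe = params@K2)
}

#' Default mutant-class parameterizations of the scheme
#'
#' The wt / moderate / severe scenario: K2 = 200 uM throughout, with
#' (K1, K5, gamma) = (0.01, 0.1, 25) for wt, (0.15, 0.5, 125) for
#' moderate mutants and (1, 10, 2500) for severe mutants.  gamma scales
#' with K5 as gamma(mut) = 25 * K5(mut)/K5(wt) so that K2 and K4 stay
#' fixed (microscopic VIM binding unperturbed by mutation).  The wt K1
#' default 0.01 realizes "K1 much less than 1" while keeping the full and
#' asymptotic Kd within a few percent of each other.
#'
#' @param K2 shared microscopic VIM Kd, uM.
#' @param K1 named numeric of up/down constants per class.
#' @param K5 named numeric of locking constants per class.
#' @param gamma_wt gamma of the wild type; mutant gammas scale with K5.
#' @return named list of [SchemeOneParams-class], one per class.
#' @export
schemeScenario <- function(K2 = 200,
                           K1 = c(wt = 0.01, moderate = 0.15, severe = 1),
                           K5 = c(wt = 0.1, moderate = 0.5, severe = 10),
                           gamma_wt = 25) {
  if (!identical(names(K1), names(K5)))
    stop("K1 and K5 must be named identically per class")
  gamma <- gamma_wt * K5 / K5[[1]]
  out <- lapply(names(K1), function(cl)
    deriveScheme(K1 = K1[[cl]], K2 = K2, gamma = gamma[[cl]], K5 = K5[[cl]]))
  names(out) <- names(K1)
  out
}

#' Speciation summary across mutant classes
#'
#' Evaluates the full scheme for each class at common totals and tabulates
#' free ligand, all species, locked and apparent-up fractions, and the
#' macroscopic Kd (full model and asymptotic limits where defined).
#'
#' @param class_params named list of [SchemeOneParams-class] (default the
#'   wt/moderate/severe scenario of [schemeScenario()]).
#' @param totals list from [mixtureTotals()]; defaults to the 50 uM
#'   protomer / 150 uM ligand study condition.
#' @return data.frame, one row per class.
#' @examples
#' mutantClassTable()
#' @export
mutantClassTable <- function(class_params = schemeScenario(),
                             totals = mixtureTotals(PT = 50, LT = 150)) {
  rows <- lapply(names(class_params), function(cl) {
    p <- class_params[[cl]]
    sp <- speciate(p, totals)
    data.frame(
      class = cl, K1 = p@K1, K5 = p@K5, gamma = p@gamma,
      L_free_uM = freeLigand(sp),
      U = sp@U, D = sp@D, UV = sp@UV, DV = sp@DV, DH = sp@DH, DHV = sp@DHV,
      f_locked = fLocked(sp), pU_apparent = pUApparent(sp),
      f_vim_bound = fVimBound(sp),
      kd_macro_uM = if (totals$LT > 0) kdMacro(p, totals) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
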