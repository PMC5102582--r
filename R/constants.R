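#' Physical constants for methyl-proton relaxation
#'
#' Fixed constants entering the relation between the methyl triple-quantum
#' buildup rate \eqn{\eta} and \eqn{S^2_{axis}\tau_c}: the proton
#' gyromagnetic ratio, the reduced Planck constant, the vacuum permeability
#' factor \eqn{\mu_0/4\pi}, the intra-methyl H-H distance and the angle
#' between the methyl threefold axis and the H-H vector (90 degrees, so
#' \eqn{[P_2(\cos\theta)]^2 = 1/4}).
#'
#' @return Named list with elements `gamma_h` (rad s^-1 T^-1), `hbar`
#'   (J s), `mu0_over_4pi` (T m A^-1), `r_hh_m` (m), `theta_axis_hh_deg`
#'   (degrees) and `p2_sq` (dimensionless).
#' @examples
#' methylConstants()$r_hh_m  # 1.813 Angstrom in metres
#' @export
methylConstants <- function() {
  list(
    gamma_h = 2.6752218744e8,
    hbar = 1.054571817e-34,
    mu0_over_4pi = 1e-7,
    r_hh_m = 1.813e-10,
    theta_axis_hh_deg = 90,
    p2_sq = 0.25
  )
}

#' Aggregate constant linking eta to S2*tauc
#'
#' \eqn{\eta = \kappa \, S^2_{axis} \tau_c} with
#' \eqn{\kappa = (9/10)(\mu_0/4\pi)^2 [P_2(\cos\theta_{axis,HH})]^2
#' \gamma_H^4 \hbar^2 / r_{HH}^6}, about 3.609e9 s^-2 when
#' \eqn{\tau_c} is in seconds.
#'
#' @param constants list as returned by [methylConstants()].
#' @return kappa in s^-2 (per second of \eqn{S^2 \tau_c}).
#' @export
kappaTQ <- function(constants = methylConstants()) {
  with(constants,
       0.9 * mu0_over_4pi^2 * p2_sq * gamma_h^4 * hbar^2 / r_hh_m^6)
}

# gyromagnetic ratios (rad s^-1 T^-1); 15N is negative
.GAMMA_N15 <- -2.7116189e7
.GAMMA_H1 <- 2.6752218744e8

# 13C/1H Larmor frequency ratio used to convert a 1H field in MHz to the
# 13C resonance frequency
.NU_RATIO_C13 <- 0.25145

# gas constant in cal mol^-1 K^-1 (free energies reported in cal/mol)
.R_CAL <- 1.9872

# default experimental temperature (50 C)
.T_DEFAULT <- 323.15
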