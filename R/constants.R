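# Physical constants (CODATA 2018) and unit conversions used throughout.
# Energies are carried in cm^-1, distances in Angstrom (converted to nm
# inside the coupling kernel), dipoles in Debye, rates in ns^-1.

.SPEED_OF_LIGHT_CM_S <- 2.99792458e10   # cm/s
.PLANCK_J_S <- 6.62607015e-34           # J s
.HBAR_J_S <- .PLANCK_J_S / (2 * pi)
.DEBYE_C_M <- 3.33564095e-30            # C m per Debye
.EPS0 <- 8.8541878128e-12               # F/m
.EV_PER_CM1 <- 1 / 8065.544             # eV per cm^-1
.CM1_PER_EV <- 8065.544                 # cm^-1 per eV
.HC_J_CM <- .PLANCK_J_S * .SPEED_OF_LIGHT_CM_S  # J cm; E[J] = hc * nu[cm^-1]

# Point-dipole prefactor: V[cm^-1] = C_dip * kappa * mu_i * mu_j / (n^2 R^3)
# with mu in Debye and R in nm. Derived from mu^2 / (4 pi eps0 R^3) / hc;
# numerically 5.034 cm^-1 nm^3 D^-2 (4 s.f.), covered by a unit test against
# the first-principles SI evaluation.
.C_DIP_CM1_NM3_D2 <- .DEBYE_C_M^2 / (4 * pi * .EPS0 * 1e-27) / .HC_J_CM

#' Physical constants used by the package
#'
#' Returns the conversion constants the coupling and rate kernels use, so the
#' conventions are inspectable: `c_dip` (cm^-1 nm^3 D^-2) in the screened
#' point-dipole coupling, `c_cm_s` (speed of light, cm/s) in the golden-rule
#' rate `k = 4 pi^2 c V^2 rho`, and `cm1_per_ev` for eV/cm^-1 conversion.
#'
#' @return Named list of constants.
#' @export
#' @examples
#' pigmentnet_constants()$c_dip  # ~5.034
pigmentnet_constants <- function() {
  list(
    c_dip = .C_DIP_CM1_NM3_D2,
    c_cm_s = .SPEED_OF_LIGHT_CM_S,
    hbar_j_s = .HBAR_J_S,
    cm1_per_ev = .CM1_PER_EV,
    debye_c_m = .DEBYE_C_M
  )
}
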