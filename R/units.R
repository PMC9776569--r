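## Physical constants and unit helpers.
## Internal units: length nm, charge e, energy kT (at the configured
## temperature), potential kT/e.

## e^2 / (4 pi eps0 kB) in nm * K; dividing by T gives the Coulomb
## prefactor C such that the potential of a unit charge in a uniform
## dielectric eps is C / (eps * r) kT/e with r in nm.
.COULOMB_NM_K <- 1.6709518e4

#' Coulomb prefactor in kT.nm/e^2 at a given temperature
#'
#' The potential of a point charge `q` (in e) at distance `r` (nm) in a
#' uniform dielectric `eps` is `coulomb_kT_nm(T) * q / (eps * r)` in kT/e.
#'
#' @param temperature temperature in K
#' @return numeric scalar, kT.nm/e^2
#' @export
coulomb_kT_nm <- function(temperature) .COULOMB_NM_K / temperature

#' kT in kcal/mol
#' @param temperature temperature in K
#' @return numeric scalar
#' @export
kT_kcal <- function(temperature) 1.98720425864083e-3 * temperature

## gas constant in kJ/(mol K), for the LJ radius criterion
.R_KJ <- 8.31446261815324e-3

## Debye screening: kappa^2 in nm^-2 for a 1:1 electrolyte of ionic
## strength I (mol/L) in a solvent of dielectric eps_s.
debye_kappa2 <- function(ionic_strength, eps_s, temperature) {
  n <- 0.602214076 * ionic_strength            # number density, nm^-3
  8 * pi * (coulomb_kT_nm(temperature) / eps_s) * n
}

LN10 <- log(10)
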