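#' Physical constants and unit helpers
#'
#' Internal units are Angstrom for length, kcal/mol for energy, and unit mass
#' per bead. Genomic coordinates are base pairs (0-based half-open); reported
#' lengths are in nm where noted.
#'
#' @name nucfold-units
NULL

# Boltzmann constant, kcal/mol/K
.kB <- 0.0019872041

# Coulomb constant in vacuum, kcal * Angstrom / (mol * e^2)
.coulomb_const <- 332.0637

# base pairs represented by one DNA bead (one B-DNA helical turn)
.bp_per_bead <- 10.5

#' Thermal energy
#'
#' @param temperature Temperature in Kelvin.
#' @return k_B T in kcal/mol.
#' @export
kBT <- function(temperature = 300) .kB * temperature

#' Debye screening length for monovalent salt
#'
#' Computed from first principles as
#' \eqn{\kappa^{-1} = (8 \pi \ell_B N_A I)^{-1/2}} with the Bjerrum length
#' \eqn{\ell_B = e^2 / (4\pi\epsilon_0 \epsilon_r k_B T)}. At 150 mM and 300 K
#' with \eqn{\epsilon_r = 78} this gives about 7.9 Angstrom.
#'
#' @param salt_mM Monovalent salt concentration in mM.
#' @param temperature Temperature in Kelvin.
#' @param dielectric Relative dielectric constant of the solvent.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(salt_mM, temperature = 300, dielectric = 78) {
  stopifnot(salt_mM > 0)
  e2_4pieps0 <- 2.566969970e-38 / 1.112650056e-10       # J m
  bjerrum <- e2_4pieps0 / (1.380649e-23 * dielectric * temperature) * 1e10 # A
  n <- (salt_mM / 1000) * 6.02214076e-4                 # ions per A^3 per species
  kappa2 <- 8 * pi * bjerrum * n
  1 / sqrt(kappa2)
}

# number of DNA beads representing `bp` base pairs
.bp_to_beads <- function(bp) as.integer(round(bp / .bp_per_bead))

#' Nucleosome molar concentration of a counted volume
#'
#' @param n_nucleosomes Number of nucleosomes.
#' @param volume_nm3 Volume in nm^3.
#' @return Concentration in micromolar.
#' @export
nucleosome_concentration <- function(n_nucleosomes, volume_nm3) {
  # 1 nm^3 = 1e-24 L
  n_nucleosomes / (6.02214076e23 * volume_nm3 * 1e-24) * 1e6
}
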