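# Physical constants (CODATA 2018). Internal unit system: length in Angstrom,
# charge in elementary charges e, potential in kT/e, force in kT/A.
.const <- list(
  e_C      = 1.602176634e-19,  # elementary charge, C
  eps0     = 8.8541878128e-12, # vacuum permittivity, F/m
  kB       = 1.380649e-23,     # Boltzmann constant, J/K
  avogadro = 6.02214076e23
)

#' Coulomb constant in thermal units
#'
#' Returns \eqn{C = e^2 / (4 \pi \varepsilon_0 k_B T)} expressed in
#' Angstrom * kT/e, i.e. the vacuum Bjerrum length at temperature `T`.
#' With this constant the potential of a point charge `q` (in e) in a uniform
#' medium of relative permittivity `eps` is `q * C / (eps * r)` kT/e at a
#' distance `r` in Angstrom. At 300 K, `C` is approximately 557 A * kT/e.
#'
#' @param temperature temperature in kelvin.
#' @return scalar, Angstrom * kT/e.
#' @export
#' @examples
#' coulomb_constant(300)
coulomb_constant <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  with(.const, e_C^2 / (4 * pi * eps0 * kB * temperature)) * 1e10
}

#' Ionic species of a salt solution
#'
#' @param concentration molar concentration (mol/L), >= 0.
#' @param valence signed integer charge of the species (non-zero).
#' @return an `ion_species` object.
#' @export
ion_species <- function(concentration, valence) {
  stopifnot(is.numeric(concentration), concentration >= 0,
            is.numeric(valence), valence == round(valence), valence != 0)
  structure(list(concentration = concentration, valence = as.integer(valence)),
            class = "ion_species")
}

#' Electroneutral salt as a pair of ion species
#'
#' Convenience constructor: a salt at concentration `c` with cation valence
#' `z_plus` and anion valence `z_minus` (negative), at concentrations chosen
#' for electroneutrality. `salt_ions(0.15)` is 150 mM 1:1 salt; divalent
#' cations (as used for tubulin work, where the cation valence is +2) are
#' `salt_ions(0.15, z_plus = 2)`.
#'
#' @param concentration cation concentration, mol/L.
#' @param z_plus cation valence (positive integer).
#' @param z_minus anion valence (negative integer).
#' @return list of two `ion_species`.
#' @export
salt_ions <- function(concentration = 0.15, z_plus = 1, z_minus = -1) {
  stopifnot(z_plus > 0, z_minus < 0)
  # n_plus * z_plus + n_minus * z_minus = 0
  n_minus <- concentration * z_plus / abs(z_minus)
  list(ion_species(concentration, z_plus), ion_species(n_minus, z_minus))
}

#' Debye-Hueckel screening parameter
#'
#' Computes the inverse screening length
#' \eqn{\kappa = \sqrt{8 \pi \lambda_B N_A I}} in 1/Angstrom, with ionic
#' strength \eqn{I = \tfrac12 \sum_i c_i z_i^2} (number density per cubic
#' Angstrom) and Bjerrum length
#' \eqn{\lambda_B = e^2/(4\pi\varepsilon_0 \varepsilon_s k_B T)}.
#' For 150 mM 1:1 salt in water (eps 80, 300 K) the screening length
#' \eqn{1/\kappa} is about 7.95 A.
#'
#' @param ions list of [ion_species()] (empty list for no salt).
#' @param eps_solvent solvent relative permittivity (> 0).
#' @param temperature kelvin.
#' @return kappa in 1/Angstrom (0 when `ions` is empty or all zero).
#' @export
#' @examples
#' 1 / debye_parameter(salt_ions(0.15), 80, 300)  # ~7.95 A
debye_parameter <- function(ions, eps_solvent = 80, temperature = 300) {
  if (!is.numeric(eps_solvent) || eps_solvent <= 0)
    stop("eps_solvent must be positive")
  if (length(ions) == 0) return(0)
  if (inherits(ions, "ion_species")) ions <- list(ions)
  ionic <- 0.5 * sum(vapply(ions, function(s) {
    stopifnot(inherits(s, "ion_species"))
    s$concentration * s$valence^2
  }, numeric(1)))
  # mol/L -> number per A^3
  n_dens <- ionic * .const$avogadro * 1e-27
  lambda_b <- coulomb_constant(temperature) / eps_solvent
  sqrt(8 * pi * lambda_b * n_dens)
}
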