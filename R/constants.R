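## Physical constants and unit conversions used across the package.
## Energies are kcal/mol, lengths Angstrom, masses amu, times ns unless noted.

# Coulomb constant in kcal*Angstrom/(mol*e^2), CHARMM convention
COULOMB_KCAL <- 332.0636

# Boltzmann constant, kcal/mol/K
KB_KCAL <- 0.0019872041

# SI constants for entropy formulas
KB_SI <- 1.380649e-23        # J/K
HBAR_SI <- 1.054571817e-34   # J*s
PLANCK_SI <- 6.62607015e-34  # J*s
AVOGADRO <- 6.02214076e23    # 1/mol
AMU_KG <- 1.66053906660e-27  # kg
KCALMOL_J <- 4184 / AVOGADRO # J per (kcal/mol)
J_PER_MOL_TO_KCAL <- 1 / 4184

# 1 M standard-state volume per molecule, Angstrom^3
STD_VOLUME_1M <- 1e27 / AVOGADRO * 1e3   # = 1660.54 A^3

#' Thermal energy k_B T
#'
#' @param temperature Temperature in kelvin.
#' @return k_B T in kcal/mol.
#' @export
kbt <- function(temperature = 300) KB_KCAL * temperature
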