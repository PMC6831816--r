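# Physical constants, all unit conversions centralised here.
# Energies are carried in kcal/mol throughout (the units of the interface
# free-energy tables); lengths in Angstrom at the user surface, metres inside
# the rate kernels.

.const <- list(
  kB          = 1.380649e-23,     # J/K
  avogadro    = 6.02214076e23,    # 1/mol
  R_kcal      = 1.9872041e-3,     # kcal/(mol K)
  R_kJ        = 8.314462618e-3,   # kJ/(mol K)
  ang         = 1e-10,            # m per Angstrom
  barrier     = exp(-3)           # dimensionless collision barrier factor
)

#' Thermal energy in kcal/mol
#'
#' @param temperature temperature in kelvin.
#' @return k_B T expressed in kcal/mol (0.596 at 300 K).
#' @export
kBT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .const$R_kcal * temperature
}

#' Convert an energy in kJ/mol to units of k_B T
#'
#' @param energy energy in kJ/mol.
#' @param temperature temperature in kelvin (default 298.15).
#' @return dimensionless energy in units of k_B T.
#' @examples
#' kJmol_to_kBT(25)   # ~10.1, a typical protein assembly barrier
#' @export
kJmol_to_kBT <- function(energy, temperature = 298.15) {
  stopifnot(is.numeric(energy), is.numeric(temperature), temperature > 0)
  energy / (.const$R_kJ * temperature)
}
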