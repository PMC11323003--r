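# CODATA 2018 physical constants (SI). Internal length unit is nm throughout;
# the scattering module converts to Angstrom at its boundary.
.const <- list(
  e_C      = 1.602176634e-19,   # elementary charge [C]
  eps0     = 8.8541878128e-12,  # vacuum permittivity [F/m]
  kB       = 1.380649e-23,      # Boltzmann constant [J/K]
  avogadro = 6.02214076e23      # [1/mol]
)

# mol/L -> number density in nm^-3 (1 L = 1e24 nm^3)
.molar_to_nm3 <- function(c_molar) c_molar * .const$avogadro * 1e-24

#' Unit conversions used at module boundaries
#'
#' @param x numeric vector of lengths.
#' @return converted numeric vector.
#' @keywords internal
#' @name units-internal
NULL

.nm_to_angstrom <- function(x) x * 10
.angstrom_to_nm <- function(x) x / 10
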