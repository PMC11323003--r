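#' Electrolyte condition
#'
#' Bundles the ion content and solvent context (relative permittivity,
#' temperature) that every closed-form electrostatic quantity depends on.
#' Formulas are evaluated in SI with the explicit `4*pi*eps0` factor; the
#' Gaussian-units shorthand `l_B = q^2 / (eps_r kB T)` corresponds to the SI
#' form `l_B = q^2 e^2 / (4 pi eps0 eps_r kB T)` used here.
#'
#' @param species a data.frame with columns `label` (character),
#'   `concentration` (mol/L, >= 0) and `valence` (integer), or a list of
#'   `list(label, concentration, valence)` triples.
#' @param epsilon_r dimensionless relative permittivity (> 0).
#' @param temperature absolute temperature in kelvin (> 0). Default 300 K,
#'   standard for lipid-bilayer simulations.
#' @return an object of class `electrolyte_condition`.
#' @examples
#' cond <- electrolyte_condition(mgcl2_species(0.05), epsilon_r = 78.5,
#'                               temperature = 298)
#' ionic_strength(cond)
#' @export
electrolyte_condition <- function(species, epsilon_r, temperature = 300) {
  if (is.list(species) && !is.data.frame(species)) {
    species <- do.call(rbind, lapply(species, function(s) {
      data.frame(label = s[[1]], concentration = as.numeric(s[[2]]),
                 valence = as.integer(s[[3]]))
    }))
  }
  stopifnot(is.data.frame(species))
  required <- c("label", "concentration", "valence")
  if (!all(required %in% names(species))) {
    stop("`species` needs columns label, concentration, valence")
  }
  if (nrow(species) < 1L) stop("at least one ion species is required")
  if (any(species$concentration < 0)) stop("concentrations must be >= 0")
  if (!is.numeric(epsilon_r) || epsilon_r <= 0) stop("epsilon_r must be > 0")
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be > 0")
  }
  structure(list(species = species, epsilon_r = epsilon_r,
                 temperature = temperature),
            class = "electrolyte_condition")
}

#' @export
print.electrolyte_condition <- function(x, ...) {
  cat(sprintf("Electrolyte: eps_r = %.3g, T = %.4g K\n",
              x$epsilon_r, x$temperature))
  for (i in seq_len(nrow(x$species))) {
    s <- x$species[i, ]
    cat(sprintf("  %-6s %8.4g M  z = %+d\n",
                s$label, s$concentration, s$valence))
  }
  invisible(x)
}

#' MgCl2 species table
#'
#' Fully dissociated MgCl2 at a given salt concentration: `c` M Mg2+ plus
#' `2c` M Cl-.
#'
#' @param conc_molar salt concentration in mol/L (default 0.05, the ~50 mM
#'   condition used throughout).
#' @return data.frame of species suitable for [electrolyte_condition()].
#' @export
mgcl2_species <- function(conc_molar = 0.05) {
  data.frame(label = c("MG", "CL"),
             concentration = c(conc_molar, 2 * conc_molar),
             valence = c(2L, -1L))
}

#' Preset: lipid-phase electrolyte condition
#'
#' 50 mM MgCl2 in the low-permittivity interbilayer environment
#' (eps_r = 40.1) at 300 K.
#' @param conc_molar MgCl2 concentration, mol/L.
#' @param temperature kelvin.
#' @return `electrolyte_condition`.
#' @export
lipid_condition <- function(conc_molar = 0.05, temperature = 300) {
  electrolyte_condition(mgcl2_species(conc_molar), epsilon_r = 40.1,
                        temperature = temperature)
}

#' Preset: aqueous-solution electrolyte condition
#'
#' 50 mM MgCl2 in the aqueous DNA-in-solution environment (eps_r = 92.2)
#' at 300 K.
#' @inheritParams lipid_condition
#' @return `electrolyte_condition`.
#' @export
solution_condition <- function(conc_molar = 0.05, temperature = 300) {
  electrolyte_condition(mgcl2_species(conc_molar), epsilon_r = 92.2,
                        temperature = temperature)
}

#' Ionic strength
#'
#' `I = 1/2 * sum_i c_i z_i^2` in mol/L.
#'
#' @param cond an [electrolyte_condition()].
#' @return ionic strength in mol/L.
#' @export
ionic_strength <- function(cond) {
  stopifnot(inherits(cond, "electrolyte_condition"))
  with(cond$species, 0.5 * sum(concentration * valence^2))
}

#' Bjerrum length
#'
#' Separation at which the Coulomb energy of two charges `q` equals `kB T`:
#' `l_B = (q e)^2 / (4 pi eps0 eps_r kB T)`. Scales as `q^2` and inversely
#' with `eps_r` and `T`.
#'
#' @param cond an [electrolyte_condition()].
#' @param charge charge in units of the elementary charge (default 1).
#' @return length in nm.
#' @export
bjerrum_length <- function(cond, charge = 1) {
  stopifnot(inherits(cond, "electrolyte_condition"))
  if (any(charge == 0)) stop("charge must be nonzero")
  num <- (charge * .const$e_C)^2
  den <- 4 * pi * .const$eps0 * cond$epsilon_r *
    .const$kB * cond$temperature
  (num / den) * 1e9
}

#' Debye screening length
#'
#' `kappa^-1 = (8 pi l_B(1e) n_I)^(-1/2)` with `n_I` the ionic strength as a
#' number density. Decreases as `I^(-1/2)`.
#'
#' @param cond an [electrolyte_condition()].
#' @return Debye length in nm.
#' @export
debye_length <- function(cond) {
  I <- ionic_strength(cond)
  if (I <= 0) {
    stop("ionic strength is zero: screening length is infinite")
  }
  lb1 <- bjerrum_length(cond, charge = 1)
  kappa2 <- 8 * pi * lb1 * .molar_to_nm3(I)
  1 / sqrt(kappa2)
}

#' Inverse Debye length
#'
#' Convenience wrapper: `kappa = 1 / debye_length(cond)` in nm^-1.
#' @inheritParams debye_length
#' @return nm^-1.
#' @export
debye_kappa <- function(cond) 1 / debye_length(cond)

#' Ion-ion coupling parameter
#'
#' `Gamma = l_B(q1, q2) / d` with `l_B(q1, q2) = |q1 q2| e^2 /
#' (4 pi eps0 eps_r kB T)`: the strength of electrostatic correlations between
#' two ions at mean separation `d` relative to thermal energy. `Gamma > 1`
#' marks the strongly coupled regime.
#'
#' @param q1,q2 ion charges in units of e.
#' @param separation mean ion-ion separation `d` in nm (> 0).
#' @param cond an [electrolyte_condition()].
#' @return dimensionless coupling parameter.
#' @examples
#' coupling_parameter(2, 2, 2.97, lipid_condition())     # ~1.87
#' coupling_parameter(2, 2, 2.89, solution_condition())  # ~0.84
#' @export
coupling_parameter <- function(q1, q2, separation, cond) {
  if (any(separation <= 0)) stop("separation must be > 0")
  bjerrum_length(cond, charge = 1) * abs(q1 * q2) / separation
}

#' Summary of electrolyte quantities
#'
#' Evaluates the standard quantities for one condition in one call; used by
#' the analysis drivers and the pipeline manifest.
#'
#' @param cond an [electrolyte_condition()].
#' @return a list: `ionic_strength_M`, `bjerrum_1e_nm`, `bjerrum_2e_nm`,
#'   `debye_length_nm`, `kappa_per_nm`.
#' @export
electrolyte_summary <- function(cond) {
  list(ionic_strength_M = ionic_strength(cond),
       bjerrum_1e_nm = bjerrum_length(cond, 1),
       bjerrum_2e_nm = bjerrum_length(cond, 2),
       debye_length_nm = debye_length(cond),
       kappa_per_nm = debye_kappa(cond))
}
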