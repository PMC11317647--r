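# Internal unit conventions: length Angstrom, time ns, charge in units of e,
# voltage mV, conductance pS, energy kcal/mol.  Inputs in kJ/mol or nm are
# converted at ingest and never stored.

#' Physical constants and unit conversions
#'
#' Constants used throughout the package, in the package's internal unit
#' system (Angstrom, ns, elementary charge, mV, pS, kcal/mol).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal mol-1 K-1 (0.0019872041).}
#'   \item{e_pS}{Conversion factor so that conductance in pS equals
#'     \code{N * z * e_pS / (t_ns * V_mV)} (1.602177e5).}
#'   \item{kJ_per_kcal}{4.184.}
#'   \item{kJnm2_to_kcalA2}{Force-constant conversion, kJ mol-1 nm-2 to
#'     kcal mol-1 A-2 (1 / 4.184 / 100).}
#' }
#' @examples
#' permConstants$kB * 310  # thermal energy at 310 K, kcal/mol
#' @export
permConstants <- list(
  kB             = 0.0019872041,
  e_pS           = 1.602177e5,
  kJ_per_kcal    = 4.184,
  kJnm2_to_kcalA2 = 1 / 4.184 / 100
)

# default van der Waals radii (Angstrom), by element
.vdw_defaults <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, NA. = 2.27, CL = 1.75, CA = 2.31, K = 2.75,
                   MG = 1.73)

# formal charges (units of e) by species-identifying atom/residue names
.ion_charges <- c(NA. = 1, SOD = 1, CL = -1, CLA = -1, CA = 2, CAL = 2,
                  K = 1, POT = 1, MG = 2)

.species_levels <- c("protein", "water-oxygen", "water-other",
                     "cation", "anion", "other")
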