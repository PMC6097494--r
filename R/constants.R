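# Physical constants and per-element tables used throughout the package.

#' Physical constants
#'
#' Boltzmann constant in the two unit systems the package needs:
#' \code{kB_kcal} in kcal/(mol K) for free energies and Boltzmann factors,
#' \code{kB_erg} in erg/K for the area-compressibility modulus (dyn/cm).
#' \code{e_over_eps0_A} is e/(eps0 * Angstrom) in volts, the conversion factor
#' that turns the double integral of a charge density in e/A^3 (yielding e/A)
#' into an electrostatic potential in volts.
#'
#' @keywords internal
.const <- list(
  kB_kcal       = 1.987204259e-3,   # kcal mol^-1 K^-1
  kB_erg        = 1.380649e-16,     # erg K^-1
  e_C           = 1.602176634e-19,  # C
  eps0          = 8.8541878128e-12, # F m^-1
  # e / (eps0 * 1 Angstrom) in volts
  e_over_eps0_A = 1.602176634e-19 / (8.8541878128e-12 * 1e-10)
)

# Elements occurring in CHARMM36 lipid/water systems.  Masses in amu,
# atomic numbers, and coherent neutron scattering lengths in fm.
# H and D scattering lengths follow the convention of membrane-scattering
# software (a_H = -3.74 fm, a_D = 6.67 fm); heavier elements use the
# standard Sears coherent values.
.elements <- data.frame(
  element = c("H", "C", "N", "O", "P"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 30.974),
  Z       = c(1L, 6L, 7L, 8L, 15L),
  nsl_fm  = c(-3.74, 6.646, 9.36, 5.803, 5.13),
  stringsAsFactors = FALSE
)

.NSL_DEUTERIUM_FM <- 6.67

#' Infer an element symbol from an atomic mass
#'
#' PSF files carry no element column; the element is recovered as the nearest
#' standard atomic mass among H, C, N, O, P within +/- 0.5 amu.  CHARMM36
#' phosphatidylcholine lipids and the three-point/four-point water models
#' contain only these elements.
#'
#' @param mass numeric vector of atomic masses (amu).
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(mass) {
  if (any(!is.finite(mass) | mass <= 0))
    stop("atomic masses must be positive and finite")
  idx <- vapply(mass, function(m) {
    d <- abs(.elements$mass - m)
    i <- which.min(d)
    if (d[i] > 0.5) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx)) {
    bad <- unique(mass[is.na(idx)])
    stop("cannot infer element for mass(es): ",
         paste(format(bad), collapse = ", "),
         " (no standard mass of H/C/N/O/P within 0.5 amu)")
  }
  .elements$element[idx]
}
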