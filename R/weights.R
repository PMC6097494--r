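# Per-atom scattering weights: electron counts, neutron scattering lengths,
# partial charges.

#' Assign per-atom scattering weights
#'
#' Builds the per-atom weight vectors that the transmembrane density profiles
#' are histograms of: electron counts (for electron density and X-ray form
#' factors), coherent neutron scattering lengths (for NSLD profiles and
#' neutron form factors), and partial charges (for the charge density feeding
#' the membrane dipole potential).
#'
#' Electron counts default to \code{Z - q} — the nuclear charge minus the
#' force-field partial charge, so polarized atoms carry fractional electron
#' numbers and the profile integral equals the true total electron count of
#' the neutral system; \code{electron_mode = "integer_Z"} uses formal atomic
#' numbers instead for sensitivity checks.
#'
#' With \code{d2o_substitution = TRUE} the hydrogens of water residues are
#' given the deuteron scattering length a_D = 6.67 fm instead of the proton
#' value a_H = -3.74 fm, emulating the heavy-water solvent of neutron
#' scattering experiments.  Lipid hydrogens are untouched:
#' phosphatidylcholines have no exchangeable protons.
#'
#' @param top a \code{Topology}.
#' @param d2o_substitution logical; substitute water hydrogens by deuterium.
#' @param electron_mode \code{"Z_minus_q"} (default) or \code{"integer_Z"}.
#' @return object of class \code{ScatteringWeights}: list with numeric
#'   vectors \code{electron_count}, \code{nsl_fm}, \code{charge} (one entry
#'   per atom, topology order).
#' @export
assign_weights <- function(top, d2o_substitution = FALSE,
                           electron_mode = c("Z_minus_q", "integer_Z")) {
  stopifnot(inherits(top, "Topology"))
  electron_mode <- match.arg(electron_mode)
  a <- top$atoms
  i <- match(a$element, .elements$element)
  if (anyNA(i))
    stop("no tabulated Z / scattering length for element(s): ",
         paste(unique(a$element[is.na(i)]), collapse = ", "),
         " (atom ", which(is.na(i))[1], ")")
  Z <- .elements$Z[i]
  electron_count <- if (electron_mode == "Z_minus_q") Z - a$charge else
    as.numeric(Z)
  nsl <- .elements$nsl_fm[i]
  if (d2o_substitution) {
    wat_h <- a$element == "H" & a$resname %in% top$water_residue_names
    nsl[wat_h] <- .NSL_DEUTERIUM_FM
  }
  structure(list(electron_count = electron_count,
                 nsl_fm = nsl,
                 charge = a$charge,
                 d2o_substitution = d2o_substitution,
                 electron_mode = electron_mode),
            class = "ScatteringWeights")
}
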