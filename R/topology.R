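# Topology container and PSF reader/writer.

DEFAULT_LIPID_RESNAMES <- c("DPPC", "POPC")
DEFAULT_WATER_RESNAMES <- c("TIP3", "TIP3P", "TIP4", "TIP4P", "WAT", "HOH", "SPC")

#' Construct a molecular topology
#'
#' A \code{Topology} bundles the per-atom records of a simulated
#' lipid/water system (names, residues, segments, masses, partial charges,
#' inferred elements) with the bookkeeping the bilayer observables need:
#' the number of lipids per leaflet \code{n_L} (the denominator of the
#' area-per-lipid), and which residue names are lipids or waters.
#'
#' @param atoms data.frame with columns \code{index} (0-based, unique),
#'   \code{name}, \code{resname}, \code{resid}, \code{segment}, \code{mass}
#'   (amu, > 0), \code{charge} (e).  An \code{element} column is added by
#'   inference from the mass when absent.
#' @param n_lipids_per_leaflet integer >= 1; lipids in one leaflet.
#' @param lipid_residue_names,water_residue_names character vectors of residue
#'   names classified as lipid / water.
#' @return object of class \code{Topology}.
#' @export
topology <- function(atoms,
                     n_lipids_per_leaflet = 1L,
                     lipid_residue_names = DEFAULT_LIPID_RESNAMES,
                     water_residue_names = DEFAULT_WATER_RESNAMES) {
  need <- c("index", "name", "resname", "resid", "segment", "mass", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$index))
    stop("atom indices must be unique within a topology")
  if (any(atoms$mass <= 0))
    stop("all atomic masses must be > 0")
  if (is.null(atoms$element))
    atoms$element <- infer_element(atoms$mass)
  n_lipids_per_leaflet <- as.integer(n_lipids_per_leaflet)
  if (is.na(n_lipids_per_leaflet) || n_lipids_per_leaflet < 1L)
    stop("n_lipids_per_leaflet must be an integer >= 1")

  top <- structure(
    list(atoms = atoms,
         n_lipids_per_leaflet = n_lipids_per_leaflet,
         lipid_residue_names = lipid_residue_names,
         water_residue_names = water_residue_names),
    class = "Topology")

  # each water residue must be net neutral (a charged "water" is a sign of a
  # mangled charge column and would corrupt charge-density profiles)
  wsel <- atoms$resname %in% water_residue_names
  if (any(wsel)) {
    key <- paste(atoms$segment[wsel], atoms$resid[wsel])
    q <- vapply(split(atoms$charge[wsel], key), sum, numeric(1))
    if (any(abs(q) > 1e-6))
      stop("water residue(s) carry net charge > 1e-6 e: ",
           paste(utils::head(names(q)[abs(q) > 1e-6], 3), collapse = ", "))
  }
  top
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      x$n_lipids_per_leaflet, "lipids/leaflet\n")
  cat("  residues:", paste(unique(x$atoms$resname), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a \code{Topology} or \code{Trajectory}.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Read a PSF topology file
#'
#' Parses the \code{!NATOM} section of an X-PLOR or CHARMM PSF file.  Both
#' dialects share the per-atom layout \code{id segname resid resname name
#' type charge mass [imove]}; they differ only in whether the atom type is a
#' string or an integer, which the whitespace parser is agnostic to.
#' Elements are inferred from the mass column (PSF has no element field).
#'
#' @param path PSF file.
#' @param n_lipids_per_leaflet lipids per leaflet; if \code{NULL}, taken as
#'   half the number of residues whose name is in
#'   \code{lipid_residue_names} (at least 1).
#' @inheritParams topology
#' @return a \code{Topology}.
#' @export
read_psf <- function(path,
                     n_lipids_per_leaflet = NULL,
                     lipid_residue_names = DEFAULT_LIPID_RESNAMES,
                     water_residue_names = DEFAULT_WATER_RESNAMES) {
  if (!file.exists(path)) stop("PSF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^PSF", lines[1]))
    stop("malformed PSF header at line 1: expected a line starting with 'PSF'")
  natom_at <- grep("!NATOM", lines, fixed = TRUE)
  if (!length(natom_at))
    stop("malformed PSF: no !NATOM section found")
  natom_at <- natom_at[1]
  natom <- suppressWarnings(as.integer(sub("^\\s*(\\d+).*", "\\1",
                                           lines[natom_at])))
  if (is.na(natom))
    stop("malformed PSF: cannot parse atom count at line ", natom_at)
  body <- lines[(natom_at + 1):(natom_at + natom)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != natom)
    stop("PSF structural error: !NATOM declares ", natom,
         " atoms but ", length(body), " atom lines were found")
  tok <- strsplit(trimws(body), "\\s+")
  nf <- lengths(tok)
  if (any(nf < 8))
    stop("PSF structural error: atom line with fewer than 8 fields at line ",
         natom_at + which(nf < 8)[1])
  m <- do.call(rbind, tok)
  atoms <- data.frame(
    index   = seq_len(natom) - 1L,
    name    = m[, 5],
    resname = m[, 4],
    resid   = as.integer(m[, 3]),
    segment = m[, 2],
    mass    = as.numeric(m[, 8]),
    charge  = as.numeric(m[, 7]),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$mass) || anyNA(atoms$charge) || anyNA(atoms$resid))
    stop("PSF structural error: non-numeric charge/mass/resid field")

  if (is.null(n_lipids_per_leaflet)) {
    sel <- atoms$resname %in% lipid_residue_names
    nres <- if (any(sel))
      length(unique(paste(atoms$segment[sel], atoms$resid[sel]))) else 0L
    n_lipids_per_leaflet <- max(1L, nres %/% 2L)
  }
  topology(atoms, n_lipids_per_leaflet,
           lipid_residue_names, water_residue_names)
}

#' Write a PSF topology file
#'
#' Emits a minimal X-PLOR-dialect PSF (\code{!NTITLE} + \code{!NATOM}
#' sections) sufficient to round-trip everything \code{\link{read_psf}}
#' parses.  Bonded sections are not written.
#'
#' @param top a \code{Topology}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_psf <- function(top, path) {
  stopifnot(inherits(top, "Topology"))
  a <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PSF EXT", "",
               sprintf("%10d !NTITLE", 1L),
               "* synthetic topology written by memphys", ""), con)
  writeLines(sprintf("%10d !NATOM", nrow(a)), con)
  writeLines(sprintf("%10d %-8s %-8d %-8s %-8s %-6s %14.6f %14.4f %8d",
                     seq_len(nrow(a)), a$segment, a$resid, a$resname,
                     a$name, a$element, a$charge, a$mass, 0L), con)
  writeLines("", con)
  invisible(path)
}
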