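# Trajectory container, multi-model PDB and binary DCD readers/writers,
# atom selection and per-frame z-recentering.

#' Construct a trajectory
#'
#' @param topology a \code{Topology}.
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, Angstrom.
#' @param box numeric matrix \code{[n_frames, 3]} of orthorhombic box lengths
#'   \code{(L_X, L_Y, L_Z)}, Angstrom.
#' @param dt_ps time between stored frames, ps.
#' @return object of class \code{Trajectory}.
#' @export
trajectory <- function(topology, coords, box, dt_ps = 1) {
  stopifnot(inherits(topology, "Topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an [n_atoms, 3, n_frames] array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coordinate count (", dim(coords)[1],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  box <- matrix(as.numeric(box), ncol = 3)
  if (nrow(box) != dim(coords)[3])
    stop("box must have one row per frame")
  if (any(box <= 0))
    stop("box lengths must be > 0")
  structure(list(topology = topology, coords = coords, box = box,
                 dt_ps = dt_ps),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, dt =", x$dt_ps, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{Trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Select atoms of a topology by residue name, atom name or segment
#'
#' @param top a \code{Topology} (or \code{Trajectory}).
#' @param resnames,names,segments optional character filters (any match).
#' @param lipids,waters logical shortcuts selecting the topology's declared
#'   lipid / water residue names.
#' @return 1-based integer row indices into the atom table.
#' @export
select_atoms <- function(top, resnames = NULL, names = NULL, segments = NULL,
                         lipids = FALSE, waters = FALSE) {
  if (inherits(top, "Trajectory")) top <- top$topology
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (lipids) resnames <- c(resnames, top$lipid_residue_names)
  if (waters) resnames <- c(resnames, top$water_residue_names)
  if (!is.null(resnames)) keep <- keep & a$resname %in% resnames
  if (!is.null(names))    keep <- keep & a$name %in% names
  if (!is.null(segments)) keep <- keep & a$segment %in% segments
  which(keep)
}

# ---------------------------------------------------------------- PDB ------

#' Read trajectory frames from a multi-model PDB or a binary DCD file
#'
#' PDB files must carry \code{CRYST1} records (one global, or one per
#' \code{MODEL}): the box is required by every profile and area observable.
#' DCD files are CHARMM/NAMD-style with the 6-element unit-cell block;
#' byte order is auto-detected.  Only orthorhombic cells are accepted.
#'
#' @param path trajectory file.
#' @param topology the matching \code{Topology}.
#' @param format \code{"pdb"} or \code{"dcd"}; default guessed from the
#'   file extension.
#' @param dt_ps time between stored frames, ps.
#' @return a \code{Trajectory}.
#' @export
read_frames <- function(path, topology, format = c("auto", "pdb", "dcd"),
                        dt_ps = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  switch(format,
         pdb = read_pdb_frames(path, topology, dt_ps),
         dcd = read_dcd(path, topology, dt_ps))
}

read_pdb_frames <- function(path, topology, dt_ps = 1) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cryst_idx <- which(rec == "CRYST1")
  if (!length(cryst_idx))
    stop("PDB has no CRYST1 record; box lengths are required")
  atom_idx <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(atom_idx)) stop("PDB contains no ATOM records")
  model_idx <- which(rec == "MODEL ")

  parse_box <- function(i) {
    v <- c(as.numeric(substr(lines[i],  7, 15)),
           as.numeric(substr(lines[i], 16, 24)),
           as.numeric(substr(lines[i], 25, 33)))
    ang <- c(as.numeric(substr(lines[i], 34, 40)),
             as.numeric(substr(lines[i], 41, 47)),
             as.numeric(substr(lines[i], 48, 54)))
    if (any(is.finite(ang) & abs(ang - 90) > 1e-3))
      stop("only orthorhombic cells are supported (CRYST1 angles != 90)")
    v
  }

  natom <- nrow(topology$atoms)
  if (!length(model_idx)) {                      # single implicit model
    if (length(atom_idx) != natom)
      stop("PDB atom count (", length(atom_idx),
           ") does not match topology (", natom, ")")
    frames <- list(atom_idx)
    boxes <- list(parse_box(cryst_idx[1]))
  } else {
    bounds <- c(model_idx, length(lines) + 1L)
    frames <- lapply(seq_along(model_idx), function(k)
      atom_idx[atom_idx > bounds[k] & atom_idx < bounds[k + 1]])
    if (any(lengths(frames) != natom))
      stop("PDB model atom count does not match topology (", natom, ")")
    boxes <- lapply(seq_along(model_idx), function(k) {
      # CRYST1 may sit just before its MODEL record or inside the block
      inside <- cryst_idx[cryst_idx > bounds[k] & cryst_idx < bounds[k + 1]]
      before <- cryst_idx[cryst_idx < bounds[k]]
      if (!length(inside) && !length(before))
        stop("no CRYST1 record available for model ", k)
      parse_box(if (length(inside)) inside[1] else max(before))
    })
  }

  nf <- length(frames)
  coords <- array(NA_real_, c(natom, 3, nf))
  for (k in seq_len(nf)) {
    l <- lines[frames[[k]]]
    coords[, 1, k] <- as.numeric(substr(l, 31, 38))
    coords[, 2, k] <- as.numeric(substr(l, 39, 46))
    coords[, 3, k] <- as.numeric(substr(l, 47, 54))
  }
  if (anyNA(coords)) stop("unparseable coordinate field in PDB")
  trajectory(topology, coords, do.call(rbind, boxes), dt_ps)
}

#' Write a trajectory as a multi-model PDB
#'
#' One \code{MODEL}/\code{ENDMDL} block per frame, each preceded by its
#' \code{CRYST1} record (orthorhombic, 90 degree angles).
#'
#' @param traj a \code{Trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  serial <- seq_len(nrow(a)) %% 100000L
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[k, 1], traj$box[k, 2], traj$box[k, 3],
                       90, 90, 90), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      serial, substr(a$name, 1, 4), substr(a$resname, 1, 4),
      a$resid %% 10000L,
      traj$coords[, 1, k], traj$coords[, 2, k], traj$coords[, 3, k],
      1, 0, substr(a$segment, 1, 4)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------- DCD ------

# Fortran unformatted records: 4-byte length, payload, 4-byte length.
.read_record <- function(con, endian) {
  n1 <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!length(n1)) stop("DCD truncated: unexpected end of file")
  payload <- readBin(con, "raw", n1)
  if (length(payload) != n1) stop("DCD truncated inside a record")
  n2 <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (!length(n2) || n2 != n1)
    stop("DCD format error: record length markers disagree")
  payload
}

.write_record <- function(con, payload_raw) {
  writeBin(length(payload_raw), con, size = 4)
  writeBin(payload_raw, con)
  writeBin(length(payload_raw), con, size = 4)
}

read_dcd <- function(path, topology, dt_ps = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  # auto-detect endianness from the 84-byte header record marker
  probe <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(probe)) stop("empty trajectory file: ", path)
  endian <- if (probe == 84) "little"
  else if (readBin(writeBin(probe, raw(), size = 4, endian = "big"),
                   "integer", size = 4, endian = "little") == 84) "big"
  else stop("DCD format error: header record is not 84 bytes in either ",
            "byte order")
  seek(con, 0)

  hdr <- .read_record(con, endian)
  magic <- rawToChar(hdr[1:4])
  if (magic != "CORD") stop("DCD format error: magic '", magic, "' != 'CORD'")
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = endian)
  nframes_hdr <- icntrl[1]
  has_cell <- icntrl[11] != 0
  .read_record(con, endian)                      # title block (ignored)
  natom <- readBin(.read_record(con, endian), "integer", 1, size = 4,
                   endian = endian)
  if (natom != nrow(topology$atoms))
    stop("DCD atom count (", natom, ") does not match topology (",
         nrow(topology$atoms), ")")
  if (!has_cell)
    stop("DCD has no unit-cell block; box lengths are required")

  frames <- list()
  boxes <- list()
  repeat {
    marker <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!length(marker)) break                  # clean EOF
    seek(con, -4, origin = "current")
    cell <- readBin(.read_record(con, endian), "double", 6, size = 8,
                    endian = endian)
    # CHARMM XTL layout: (A, cos(g)|g, B, cos(b)|b, cos(a)|a, C)
    off <- cell[c(2, 4, 5)]
    if (!all(abs(off) < 1e-9 | abs(off - 90) < 1e-6))
      stop("only orthorhombic DCD cells are supported")
    boxes[[length(boxes) + 1L]] <- cell[c(1, 3, 6)]
    xyz <- vapply(1:3, function(d)
      readBin(.read_record(con, endian), "double", natom, size = 4,
              endian = endian),
      numeric(natom))
    frames[[length(frames) + 1L]] <- xyz
  }
  if (!length(frames)) stop("DCD contains no frames")
  if (nframes_hdr > 0 && length(frames) != nframes_hdr)
    warning("DCD header declares ", nframes_hdr, " frames; read ",
            length(frames))
  coords <- array(unlist(frames), c(natom, 3, length(frames)))
  trajectory(topology, coords, do.call(rbind, boxes), dt_ps)
}

#' Write a trajectory as a CHARMM/NAMD-style binary DCD
#'
#' Single-precision coordinates with a 6-element unit-cell block per frame
#' (orthorhombic: cosines written as 0).  Native byte order.
#'
#' @param traj a \code{Trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L; icntrl[20] <- 24L
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4))
  .write_record(con, hdr)
  title <- sprintf("%-80s", "synthetic trajectory written by memphys")
  .write_record(con, c(writeBin(1L, raw(), size = 4), charToRaw(title)))
  .write_record(con, writeBin(nrow(traj$topology$atoms), raw(), size = 4))
  for (k in seq_len(nf)) {
    cell <- c(traj$box[k, 1], 0, traj$box[k, 2], 0, 0, traj$box[k, 3])
    .write_record(con, writeBin(cell, raw(), size = 8))
    for (d in 1:3)
      .write_record(con, writeBin(as.numeric(traj$coords[, d, k]), raw(),
                                  size = 4))
  }
  invisible(path)
}

# ---------------------------------------------------------- recentering ----

#' Recenter trajectory frames on a reference z center of mass
#'
#' Shifts every frame along z so the mass-weighted center of the reference
#' selection sits at z = 0 (the bilayer midplane convention used by all
#' profile observables), then wraps z into \code{[-L_Z/2, L_Z/2)}.
#' x and y are untouched.  Idempotent for in-box systems.
#'
#' @param traj a \code{Trajectory}.
#' @param reference_selection 1-based atom indices; default all lipid atoms
#'   (all atoms if the topology declares no lipids).
#' @return the recentered \code{Trajectory}.
#' @export
recenter_frames <- function(traj, reference_selection = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  if (is.null(reference_selection)) {
    reference_selection <- select_atoms(traj, lipids = TRUE)
    if (!length(reference_selection))
      reference_selection <- seq_len(nrow(traj$topology$atoms))
  }
  if (!length(reference_selection))
    stop("reference selection is empty")
  m <- traj$topology$atoms$mass[reference_selection]
  w <- m / sum(m)
  for (k in seq_len(n_frames(traj))) {
    z <- traj$coords[, 3, k]
    com <- sum(w * z[reference_selection])
    z <- z - com
    Lz <- traj$box[k, 3]
    traj$coords[, 3, k] <- (z + Lz / 2) %% Lz - Lz / 2
  }
  traj
}
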