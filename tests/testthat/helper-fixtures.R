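# Fixtures built in code: a hand-written water PSF, small direct-constructed
# topologies/trajectories, and shared constants.

KB_KCAL <- 1.987204259e-3

# minimal X-PLOR PSF with `nwat` mTIP3P-like waters
write_water_psf <- function(path, nwat = 1) {
  lines <- c("PSF", "", sprintf("%8d !NTITLE", 1L), " REMARKS test fixture",
             "", sprintf("%8d !NATOM", 3L * nwat))
  id <- 0L
  for (r in seq_len(nwat)) {
    q <- c(-0.834, 0.417, 0.417)
    m <- c(15.9994, 1.008, 1.008)
    nm <- c("OH2", "H1", "H2")
    ty <- c("OT", "HT", "HT")
    for (a in 1:3) {
      id <- id + 1L
      lines <- c(lines, sprintf("%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d",
                                id, "WAT", r, "TIP3", nm[a], ty[a], q[a], m[a], 0L))
    }
  }
  writeLines(c(lines, ""), path)
  path
}

# a bare topology of n atoms of one element
make_top <- function(n, element = "O", charge = 0, resname = "GRP",
                     n_L = 1L, water = FALSE) {
  mass <- unname(c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974)[element])
  topology(data.frame(index = seq_len(n) - 1L, name = element,
                      resname = resname, resid = seq_len(n), segment = "A",
                      mass = mass, charge = charge,
                      stringsAsFactors = FALSE),
           n_lipids_per_leaflet = n_L,
           lipid_residue_names = "LIP",
           water_residue_names = if (water) resname else "TIP3")
}

# trajectory with explicit coordinates: coords [n, 3] or [n, 3, f]
make_traj <- function(top, coords, box = c(40, 40, 110)) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  nf <- dim(coords)[3]
  trajectory(top, coords, matrix(rep(box, each = nf), nf, 3))
}
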