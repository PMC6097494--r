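# Topology / trajectory I/O, scattering weights, recentering.

test_that("PSF parsing recovers charges, masses and inferred elements", {
  psf <- write_water_psf(withr::local_tempfile(fileext = ".psf"), nwat = 5)
  top <- read_psf(psf, n_lipids_per_leaflet = 2)
  expect_equal(nrow(top$atoms), 15)
  expect_equal(top$atoms$charge[1:3], c(-0.834, 0.417, 0.417))
  expect_equal(sum(top$atoms$charge[1:3]), 0)
  expect_equal(top$atoms$element[1:3], c("O", "H", "H"))
  expect_equal(top$n_lipids_per_leaflet, 2L)   # declared value passes through
})

test_that("malformed PSF inputs raise structural errors", {
  f <- withr::local_tempfile(fileext = ".psf")
  writeLines(c("NOT A PSF", "junk"), f)
  expect_error(read_psf(f), "malformed PSF header")
  writeLines(c("PSF", "", "       5 !NATOM",
               "       1 A    1    W    O    OT     0.0   15.999   0"), f)
  expect_error(read_psf(f), "structural error")
  expect_error(read_psf(file.path(tempdir(), "nope.psf")), "not found")
})

test_that("synthetic PSF round-trips through write_psf/read_psf", {
  spec <- bilayer_spec(
    data.frame(name = c("PHOS", "WATR"), count = c(20, 50),
               element = c("P", "O"), charge = c(0, 0),
               z_mean = c(18, 40), z_sigma = c(3, 8)),
    area_mean = 2260, n_frames = 1, seed = 4)
  top <- gen_bilayer_trajectory(spec)$topology
  f <- withr::local_tempfile(fileext = ".psf")
  write_psf(top, f)
  top2 <- read_psf(f, n_lipids_per_leaflet = top$n_lipids_per_leaflet)
  expect_equal(top2$atoms$charge, top$atoms$charge)
  expect_equal(top2$atoms$mass, top$atoms$mass, tolerance = 1e-4)
  expect_equal(top2$atoms$resname, top$atoms$resname)
  expect_equal(top2$atoms$element, top$atoms$element)
})

test_that("multi-model PDB parses frames and per-frame boxes", {
  top <- make_top(2)
  coords <- array(c(1, 2, 0, 0, 5, -5, 1.5, 2.5, 0, 0, 6, -6), c(2, 3, 2))
  traj <- trajectory(top, coords,
                     matrix(c(44, 44, 110, 44, 44, 110), 2, 3, byrow = TRUE))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, f)
  rt <- read_frames(f, top, format = "pdb")
  expect_equal(n_frames(rt), 2)
  expect_equal(rt$box[1, ], c(44, 44, 110))
  expect_equal(rt$coords, traj$coords, tolerance = 1e-3)  # %.3f in PDB
})

test_that("PDB without CRYST1 and empty files are rejected", {
  top <- make_top(1)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               "ATOM      1  O   GRP     1       1.000   1.000   1.000  1.00  0.00",
               "ENDMDL"), f)
  expect_error(read_frames(f, top), "CRYST1")
  e <- withr::local_tempfile(fileext = ".pdb")
  file.create(e)
  expect_error(read_frames(e, top), "empty")
})

test_that("DCD round-trip is bit-exact at single precision", {
  top <- make_top(7)
  set.seed(9)
  coords <- array(rnorm(7 * 3 * 10, sd = 20), c(7, 3, 10))
  box <- cbind(runif(10, 40, 48), runif(10, 40, 48), rep(110, 10))
  traj <- trajectory(top, coords, box)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, f)
  rt <- read_frames(f, top, format = "dcd")
  expect_equal(n_frames(rt), 10)
  # storage is float32: compare against the float32-rounded original
  f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4),
                             "double", length(x), size = 4)
  expect_identical(as.vector(rt$coords), f32(coords))
  expect_equal(rt$box, traj$box)   # cell block is float64
})

test_that("written DCD agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  top <- make_top(5)
  set.seed(13)
  coords <- array(rnorm(5 * 3 * 4, sd = 15), c(5, 3, 4))
  traj <- trajectory(top, coords, matrix(rep(c(45, 45, 100), 4), 4, 3,
                                         byrow = TRUE))
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, f)
  ext <- bio3d::read.dcd(f, verbose = FALSE)  # frames x (x1 y1 z1 x2 ...)
  ours <- read_frames(f, top, format = "dcd")
  for (k in 1:4)
    expect_equal(as.numeric(t(ours$coords[, , k])), as.numeric(ext[k, ]),
                 tolerance = 1e-6)
})

test_that("scattering weights follow Z - q, with D2O touching only water H", {
  psf <- write_water_psf(withr::local_tempfile(fileext = ".psf"))
  top <- read_psf(psf)
  w <- assign_weights(top)
  expect_equal(w$electron_count[1], 8 + 0.834)        # O with q = -0.834
  expect_equal(sum(w$electron_count), 8 + 2 * 1 - 0)  # sum Z - sum q
  expect_equal(w$nsl_fm[2], -3.74)
  wd <- assign_weights(top, d2o_substitution = TRUE)
  expect_equal(wd$nsl_fm[2:3], c(6.67, 6.67))
  expect_equal(wd$electron_count, w$electron_count)

  # lipid hydrogens are NOT substituted (no exchangeable protons)
  lip <- topology(data.frame(index = 0:1, name = c("C2", "H2R"),
                             resname = "POPC", resid = 1, segment = "MEMB",
                             mass = c(12.011, 1.008), charge = c(0, 0)),
                  n_lipids_per_leaflet = 1)
  wl <- assign_weights(lip, d2o_substitution = TRUE)
  expect_equal(wl$nsl_fm[2], -3.74)
  wi <- assign_weights(top, electron_mode = "integer_Z")
  expect_equal(wi$electron_count[1:3], c(8, 1, 1))
})

test_that("element inference rejects masses far from H/C/N/O/P", {
  expect_error(infer <- topology(
    data.frame(index = 0, name = "X", resname = "GRP", resid = 1,
               segment = "A", mass = 35.45, charge = 0)),
    "cannot infer element")
})

test_that("recentering zeroes the reference COM and is idempotent", {
  top <- make_top(4, resname = "LIP")
  top$lipid_residue_names <- "LIP"
  base <- cbind(runif(4, 0, 40), runif(4, 0, 40), c(-10, -2, 3, 9))
  offs <- c(5, -7.3, 0.01)
  coords <- array(NA_real_, c(4, 3, 3))
  for (k in 1:3) coords[, , k] <- base + cbind(0, 0, rep(offs[k], 4))
  traj <- make_traj(top, coords)
  rc <- recenter_frames(traj)
  for (k in 1:3)
    expect_lt(abs(sum(rc$coords[, 3, k] * top$atoms$mass) /
                    sum(top$atoms$mass)), 1e-9)
  rc2 <- recenter_frames(rc)
  expect_equal(rc2$coords, rc$coords)
  expect_error(recenter_frames(traj, integer(0)), "empty")
})
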