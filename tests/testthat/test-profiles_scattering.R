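# Density profiles, form factors, dipole potential, experimental comparison.

test_that("a single atom lands in one bin with weight / bin volume", {
  top <- make_top(1, element = "O", charge = -0.834)
  traj <- make_traj(top, matrix(c(5, 5, 0.1), 1), box = c(40, 40, 110))
  prof <- density_profile(traj, assign_weights(top), "electron",
                          bin_width = 0.2)
  expect_equal(sum(prof$value > 0), 1)
  expect_equal(max(prof$value), 8.834 / (40 * 40 * 0.2))
})

test_that("profile of a Gaussian slab matches the analytic density", {
  n <- 1e5
  spec <- bilayer_spec(
    data.frame(name = "WATR", count = n, element = "O", charge = 0,
               z_mean = 0, z_sigma = 5),
    area_mean = 1600, Lz = 80, n_frames = 1, seed = 8)
  g <- gen_bilayer_trajectory(spec)
  prof <- density_profile(g$trajectory, assign_weights(g$topology),
                          "electron", bin_width = 0.5)
  A <- n * 8 / (1600 * 5 * sqrt(2 * pi))
  expected <- A * exp(-prof$z^2 / 50)
  sel <- abs(prof$z) < 15
  expect_lt(max(abs(prof$value[sel] - expected[sel])) / A, 0.03)
})

test_that("weight totals are conserved by the binning", {
  spec <- bilayer_spec(
    data.frame(name = c("PHOS", "WATR"), count = c(200, 500),
               element = c("P", "O"), charge = c(0.4, -0.16),
               z_mean = c(18, 35), z_sigma = c(3, 10)),
    area_mean = 2000, area_var = 400, Lz = 100, n_frames = 5, seed = 12)
  g <- gen_bilayer_trajectory(spec)
  w <- assign_weights(g$topology)
  prof <- density_profile(g$trajectory, w, "electron", bin_width = 0.2)
  total <- sum(prof$value) * prof$bin_width * prof$mean_area
  expect_equal(total, sum(w$electron_count), tolerance = 1e-6)

  # net-neutral charge profile integrates to zero
  spec_n <- bilayer_spec(
    data.frame(name = c("PLUS", "MINS"), count = c(300, 300),
               element = c("P", "O"), charge = c(0.3, -0.3),
               z_mean = c(15, 18), z_sigma = c(2, 3)),
    area_mean = 2000, Lz = 100, n_frames = 2, seed = 13)
  gn <- gen_bilayer_trajectory(spec_n)
  pn <- density_profile(gn$trajectory, assign_weights(gn$topology), "charge",
                        bin_width = 0.2)
  expect_lt(abs(sum(pn$value) * pn$bin_width), 1e-9)
})

test_that("symmetrized profile of an even distribution matches raw profile", {
  spec <- bilayer_spec(
    data.frame(name = "PHOS", count = 5e4, element = "P", charge = 0,
               z_mean = 18, z_sigma = 3),
    area_mean = 2000, Lz = 100, n_frames = 1, seed = 21, mirror = TRUE)
  g <- gen_bilayer_trajectory(spec)
  prof <- density_profile(g$trajectory, assign_weights(g$topology),
                          "electron", bin_width = 0.5)
  sym <- symmetrize_profile(prof)
  expect_lt(max(abs(sym$value - prof$value)) / max(prof$value), 0.1)
})

test_that("form factor of a Gaussian contrast equals its Fourier transform", {
  z <- seq(-40, 40, by = 0.1)
  A <- 0.1; sig <- 5
  prof <- as_density_profile(z, A * exp(-z^2 / (2 * sig^2)) + 0.333,
                             kind = "electron")
  q <- seq(0, 1, by = 0.005)
  ff <- form_factor(prof, rho_w = 0.333, q_grid = q)
  exact <- A * sig * sqrt(2 * pi) * exp(-q^2 * sig^2 / 2)
  expect_lt(max(abs(ff$F - exact) / exact), 1e-4)
  expect_equal(ff$F[1], 1.2533, tolerance = 1e-4)   # A sigma sqrt(2 pi)

  flat <- as_density_profile(z, rep(0.333, length(z)), kind = "electron")
  expect_true(all(form_factor(flat, rho_w = 0.333, q_grid = q)$F == 0))
})

test_that("|F(0)| equals |integral of contrast| and sine term vanishes for even profiles", {
  z <- seq(-30, 30, by = 0.2)
  set.seed(6)
  ragged <- runif(length(z))
  prof <- as_density_profile(z, ragged, kind = "electron")
  ff0 <- form_factor(prof, rho_w = 0.2, q_grid = 0, symmetrize = FALSE)
  expect_equal(ff0$F, abs(pracma::trapz(z, ragged - 0.2)))

  even <- as_density_profile(z, exp(-z^2 / 40), kind = "electron")
  ff <- form_factor(even, rho_w = 0, q_grid = seq(0, 1, 0.01))
  expect_lt(max(abs(ff$F_im)), 1e-10 * max(ff$F))
  expect_equal(ff$F, abs(ff$F_re))
})

test_that("neutron form factor of a hydrocarbon slab shows box-contrast nodes", {
  # uniform D2O background: zero contrast everywhere -> |F| = 0
  z <- seq(-40, 40, by = 0.1)
  rho_d2o <- 0.0635
  unif <- as_density_profile(z, rep(rho_d2o, length(z)), kind = "nsl")
  expect_true(all(form_factor(unif, rho_w = rho_d2o)$F == 0))

  # negative-NSL slab of half-width a in D2O: |F| ~ |2 c sin(qa)/q|,
  # first node at q = pi / a
  a <- 15; contrast <- -0.06
  slab <- as_density_profile(z, ifelse(abs(z) <= a, rho_d2o + contrast,
                                       rho_d2o), kind = "nsl")
  q <- seq(0.01, 0.5, by = 0.001)
  ff <- form_factor(slab, rho_w = rho_d2o, q_grid = q)
  exact <- abs(2 * contrast * sin(q * a) / q)
  expect_lt(max(abs(ff$F - exact)), 5e-3 * max(exact))
  win <- q > 0.15 & q < 0.25                  # bracket of the first node
  node <- q[win][which.min(ff$F[win])]
  expect_equal(node, pi / a, tolerance = 0.02)
})

test_that("dipole potential reproduces the parallel-plate capacitor", {
  z <- seq(-40, 40, by = 0.2)
  dz <- 0.2
  d <- 30; sigma_s <- 0.01                    # e/A^2 per sheet
  zeta <- numeric(length(z))
  zeta[which.min(abs(z + d / 2))] <- -sigma_s / dz
  zeta[which.min(abs(z - d / 2))] <- +sigma_s / dz
  prof <- as_density_profile(z, zeta, kind = "charge")
  pot <- dipole_potential(prof, z0 = -40)
  expect_equal(pot$phi[1], 0)
  e_over_eps0 <- 1.602176634e-19 / (8.8541878128e-12 * 1e-10)
  plateau <- sigma_s * d * e_over_eps0        # volts
  right <- pot$phi[z > d / 2 + 1]
  expect_lt(max(abs(right - plateau)) / plateau, 0.005)
  left <- pot$phi[z < -d / 2 - 1]
  expect_lt(max(abs(left)) / plateau, 1e-9)

  # linearity: doubling the charge density doubles phi everywhere
  pot2 <- dipole_potential(as_density_profile(z, 2 * zeta, kind = "charge"),
                           z0 = -40)
  expect_equal(pot2$phi, 2 * pot$phi)

  # zero charge -> zero potential; net charge -> error
  zero <- dipole_potential(as_density_profile(z, numeric(length(z)),
                                              kind = "charge"))
  expect_true(all(zero$phi == 0))
  bad <- as_density_profile(z, rep(1e-4, length(z)), kind = "charge")
  expect_error(dipole_potential(bad), "net charge")
})

test_that("form-factor comparison recovers scale and noise level", {
  q <- seq(0.02, 0.8, by = 0.01)
  Fsim <- 2 * exp(-q^2 * 12) + 0.05
  ff <- structure(list(q = q, F = Fsim, kind = "electron"),
                  class = "FormFactor")
  ident <- compare_form_factors(ff, data.frame(q = q, F = Fsim))
  expect_equal(ident$k, 1)
  expect_equal(ident$rms, 0)
  half <- compare_form_factors(ff, data.frame(q = q, F = Fsim / 2))
  expect_equal(half$k, 2)
  expect_lt(half$rms, 1e-12)

  sigma_n <- 0.03
  set.seed(14)
  noisy <- compare_form_factors(
    ff, data.frame(q = q, F = Fsim + rnorm(length(q), 0, sigma_n)),
    scale = "fixed")
  expect_lt(abs(noisy$rms / sigma_n - 1), 0.2)
  expect_error(
    compare_form_factors(ff, data.frame(q = 2 + q, F = Fsim)),
    "overlap")
})

test_that("experimental tables read with comments and round-trip profiles", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q |F| (synthetic)", "0.05 1.2", "0.10 0.8"), f)
  tab <- read_form_factor_table(f)
  expect_equal(tab$q, c(0.05, 0.10))
  z <- seq(-5, 5, 0.5)
  prof <- as_density_profile(z, exp(-z^2), kind = "electron")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, out)
  back <- utils::read.table(out, comment.char = "#")
  expect_equal(back[[1]], z)
  expect_equal(back[[2]], prof$value, tolerance = 1e-9)
})
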