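# WHAM, restrained-coordinate diffusivity, solubility-diffusion integral.

test_that("umbrella windows validate and discard equilibration", {
  w <- umbrella_window(0, 2.5, seq_len(600), equilibration_fraction = 1 / 6)
  expect_length(w$samples, 500)
  expect_equal(w$samples[1], 101)
  expect_error(umbrella_window(0, -1, seq_len(600)), "spring constant")
  expect_error(umbrella_window(0, 2.5, seq_len(90),
                               equilibration_fraction = 0), "100")
})

test_that("single unbiased window inverts to the Boltzmann potential", {
  # w(z) = 0.05 z^2 => Boltzmann density is Gaussian, var = kB T / 0.1
  T <- 298; kT <- KB_KCAL * T
  set.seed(23)
  z <- rnorm(1e6, 0, sqrt(kT / 0.1))
  win <- umbrella_window(0, 0, z, equilibration_fraction = 0)
  pmf <- suppressWarnings(wham_pmf(list(win), T, bin_width = 0.25,
                                   offset = "min"))
  sel <- abs(pmf$z) <= 6 & is.finite(pmf$w)
  resid <- pmf$w[sel] - 0.05 * pmf$z[sel]^2
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.05)
})

test_that("two identical windows equal one window with concatenated samples", {
  set.seed(3)
  s <- rnorm(5000, 1, 0.6)
  w1 <- umbrella_window(1, 2.5, s, equilibration_fraction = 0)
  w2 <- umbrella_window(1, 2.5, c(s, s), equilibration_fraction = 0)
  a <- suppressWarnings(wham_pmf(list(w1, w1), 298, offset = "min"))
  b <- suppressWarnings(wham_pmf(list(w2), 298, offset = "min"))
  expect_equal(a$w, b$w, tolerance = 1e-8)
})

test_that("offset conventions differ only by a constant", {
  set.seed(4)
  wins <- lapply(c(-1, 0, 1), function(c0)
    umbrella_window(c0, 2.5, rnorm(4000, c0, 0.5),
                    equilibration_fraction = 0))
  a <- suppressWarnings(wham_pmf(wins, 298, offset = "min"))
  b <- suppressWarnings(wham_pmf(wins, 298, offset = "none"))
  d <- a$w - b$w
  expect_lt(diff(range(d, na.rm = TRUE)), 1e-10)
})

test_that("WHAM recovers a harmonic potential from overlapping windows", {
  spec <- permeation_model_spec(
    w = function(z) 0.05 * z^2, D = 0.3,
    centers = seq(-20, 20, by = 1), k = 2.5,
    n_steps = 3e4, dt = 0.02, thin = 3L, seed = 19)
  gl <- gen_langevin_windows(spec, restraint_k = NULL)
  wins <- lapply(gl$umbrella, function(u)
    umbrella_window(u$center, u$k, u$samples,
                    equilibration_fraction = 1 / 6, dt_ps = u$dt_ps))
  pmf <- wham_pmf(wins, 298, bin_width = 0.5, offset = "min")
  expect_lt(pmf$final_residual, 1e-8)
  sel <- abs(pmf$z) <= 18 & is.finite(pmf$w)
  resid <- pmf$w[sel] - 0.05 * pmf$z[sel]^2
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.15)
})

test_that("diffusivity estimator recovers the OU closed form D = sigma^2/tau", {
  T <- 298; k <- 20
  sig2 <- KB_KCAL * T / k                   # 0.02961 A^2
  expect_equal(sig2, 0.02961, tolerance = 1e-4)
  D <- 0.3
  tau <- sig2 / D                            # 0.0987 ps
  dt <- tau / 10
  z <- gen_ou_series(2e5, sig2, tau, dt, seed = 11)
  est <- diffusivity_gle(z, dt, k = k, temperature_K = T)
  expect_lt(abs(est$D_A2ps / D - 1), 0.10)
  expect_equal(est$D_cm2s, est$D_A2ps * 1e-4)
})

test_that("degenerate diffusivity inputs are flagged", {
  set.seed(2)
  expect_warning(diffusivity_gle(rnorm(5000), dt = 0.01), "under-resolved")
  expect_error(diffusivity_gle(rep(1, 5000), dt = 0.01), "non-dissipative")
  expect_error(diffusivity_gle(rnorm(100), dt = 0.01), "too short")
})

test_that("permeability closed forms: flat and square-barrier profiles", {
  T <- 298; kT <- KB_KCAL * T
  z <- seq(-30, 30, by = 0.2)
  flat <- structure(list(z = z, w = rep(0, length(z)), temperature_K = T),
                    class = "PMFProfile")
  p <- permeability_sd(flat, 1e-5)
  expect_equal(p$P_m, 1e-5 / (60 * 1e-8), tolerance = 1e-4)

  zf <- seq(-30, 30, by = 0.01)
  w0 <- 5
  sq <- structure(list(z = zf, w = ifelse(abs(zf) < 15, w0, 0),
                       temperature_K = T), class = "PMFProfile")
  p2 <- suppressWarnings(permeability_sd(sq, 1e-5))
  R_exact <- (30e-8 + 30e-8 * exp(w0 / kT)) / 1e-5
  expect_lt(abs(p2$P_m * R_exact - 1), 1e-3)
  expect_equal(p2$resistivity, 1 / p2$P_m)
})

test_that("permeability scales and orders as the model demands", {
  T <- 298; kT <- KB_KCAL * T
  zf <- seq(-30, 30, by = 0.05)
  pm <- function(w0, D = 1e-5) {
    pmf <- structure(list(z = zf, w = w0 * exp(-zf^2 / 100),
                          temperature_K = T), class = "PMFProfile")
    suppressWarnings(permeability_sd(pmf, D))$P_m
  }
  barriers <- seq(0, 8, by = 2)
  ps <- vapply(barriers, pm, numeric(1))
  expect_true(all(diff(ps) < 0))             # monotonic in barrier height
  expect_equal(pm(4, 2e-5), 2 * pm(4, 1e-5)) # linear in D

  # shifting w by a constant multiplies 1/P by exp(c/kT) exactly
  pmf0 <- structure(list(z = zf, w = rep(0, length(zf)), temperature_K = T),
                    class = "PMFProfile")
  pmfc <- structure(list(z = zf, w = rep(1.5, length(zf)), temperature_K = T),
                    class = "PMFProfile")
  p0 <- permeability_sd(pmf0, 1e-5)$P_m
  pc <- suppressWarnings(permeability_sd(pmfc, 1e-5))$P_m
  expect_equal(p0 / pc, exp(1.5 / kT), tolerance = 1e-10)

  interp_D <- diffusivity_profile(c(-30, 0, 30), c(0.1, 0.3, 0.1))
  expect_error(diffusivity_profile(c(0, 1), c(0.1, -0.2)), "> 0")
  expect_s3_class(permeability_sd(pmf0, interp_D), "PermeabilityResult")
})

test_that("umbrella window files and manifests round-trip", {
  dir <- withr::local_tempdir()
  w <- umbrella_window(-12.5, 2.5, rnorm(500, -12.5, 0.5),
                       equilibration_fraction = 0, dt_ps = 0.04)
  f <- file.path(dir, "win.dat")
  write_umbrella_window(w, f)
  r <- read_umbrella_window(f)
  expect_equal(r$center, -12.5)
  expect_equal(r$k, 2.5)
  expect_equal(r$dt_ps, 0.04)
  expect_equal(r$samples, w$samples, tolerance = 1e-7)
  writeLines(c("# manifest", "win.dat"), file.path(dir, "manifest.txt"))
  set <- read_umbrella_set(file.path(dir, "manifest.txt"))
  expect_length(set, 1)
  expect_equal(set[[1]]$center, -12.5)
})
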