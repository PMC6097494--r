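# Synthetic-data generators with analytic ground truth: Gaussian-slab bilayer
# trajectories, overdamped Langevin umbrella/restrained series on a declared
# w(z)/D(z), and lambda-coupled harmonic-oscillator free-energy samples.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Specify a synthetic Gaussian-slab bilayer
#'
#' Each group is a set of identical pseudo-atoms whose z positions are drawn
#' from a Gaussian slab (mean, sigma); x and y are uniform over the box.
#' Groups with nonzero z mean are mirrored at -z when
#' \code{mirror = TRUE}, emulating a symmetric bilayer.  Box areas fluctuate
#' as a Gaussian with the declared mean and variance at fixed L_Z.
#'
#' @param groups data.frame with columns \code{name}, \code{count},
#'   \code{element} (H/C/N/O/P), \code{charge} (e), \code{z_mean},
#'   \code{z_sigma} (Angstrom), optional \code{resname} (default the group
#'   name) and logical \code{water} (zero-charge groups only).
#' @param area_mean,area_var mean and variance of the lateral box area L_X *
#'   L_Y, Angstrom^2 (L_X = L_Y = sqrt(area)).
#' @param Lz fixed box height, Angstrom.
#' @param n_lipids_per_leaflet declared n_L for area observables.
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param mirror mirror off-center groups at -z.
#' @param ch optional list \code{(S, n_pairs, bond = 1.09)}: adds C-H
#'   pseudo-pair atoms whose bonds all sit on the cone at the angle
#'   theta = acos(sqrt((2 S + 1)/3)), so the order parameter is exactly
#'   \code{S}; azimuths are uniform.
#' @return object of class \code{BilayerSpec}.
#' @export
bilayer_spec <- function(groups, area_mean, area_var = 0, Lz = 110,
                         n_lipids_per_leaflet = 1L, n_frames = 10L,
                         seed = 1L, mirror = TRUE, ch = NULL) {
  need <- c("name", "count", "element", "charge", "z_mean", "z_sigma")
  if (!all(need %in% names(groups)))
    stop("groups needs columns: ", paste(need, collapse = ", "))
  if (any(groups$count < 1)) stop("group counts must be >= 1")
  if (any(groups$z_sigma <= 0)) stop("group z_sigma must be > 0")
  if (area_var < 0) stop("area variance must be >= 0")
  if (is.null(groups$resname)) groups$resname <- groups$name
  if (is.null(groups$water)) groups$water <- FALSE
  if (any(groups$water & groups$charge != 0))
    stop("water-flagged groups must carry zero charge ",
         "(single-atom residues must be neutral)")
  if (!is.null(ch)) {
    if (ch$S < -0.5 || ch$S > 1) stop("declared S must lie in [-0.5, 1]")
    if (is.null(ch$bond)) ch$bond <- 1.09
  }
  structure(list(groups = groups, area_mean = area_mean, area_var = area_var,
                 Lz = Lz, n_lipids_per_leaflet = n_lipids_per_leaflet,
                 n_frames = as.integer(n_frames), seed = seed,
                 mirror = mirror, ch = ch),
            class = "BilayerSpec")
}

#' Generate a synthetic bilayer trajectory
#'
#' Draws atoms independently per frame from the spec's z-Gaussians (the
#' density profile of each group is analytically
#' count/(area sigma sqrt(2 pi)) exp(-(z - mu)^2 / 2 sigma^2)), with Gaussian
#' box-area fluctuations.  Deterministic under the spec's seed.
#'
#' @param spec a \code{BilayerSpec}.
#' @param write_dir if non-NULL, also writes \code{system.psf},
#'   \code{traj.pdb} and \code{traj.dcd} there.
#' @return list with \code{topology}, \code{trajectory}, \code{ch_pairs}
#'   (data.frame of label/c_index/h_index, or NULL), and \code{spec}.
#' @export
gen_bilayer_trajectory <- function(spec, write_dir = NULL) {
  stopifnot(inherits(spec, "BilayerSpec"))
  g <- spec$groups
  if (spec$mirror) {
    off <- g[g$z_mean != 0, , drop = FALSE]
    if (nrow(off)) {
      off$z_mean <- -off$z_mean
      off$name <- paste0(off$name, "m")
      off$resname <- g$resname[g$z_mean != 0]   # same residue class
      g <- rbind(g, off)
    }
  }

  counts <- g$count
  natom_g <- sum(counts)
  n_ch <- if (!is.null(spec$ch)) spec$ch$n_pairs else 0L
  natom <- natom_g + 2L * n_ch

  atoms <- data.frame(
    index = seq_len(natom) - 1L,
    name = c(rep(substr(g$name, 1, 4), counts),
             if (n_ch) rep(c("CS", "HS"), n_ch)),
    resname = c(rep(g$resname, counts), if (n_ch) rep("CHP", 2L * n_ch)),
    resid = c(seq_len(natom_g),
              if (n_ch) natom_g + rep(seq_len(n_ch), each = 2L)),
    segment = "SYN",
    mass = NA_real_,
    charge = c(rep(g$charge, counts), if (n_ch) rep(0, 2L * n_ch)),
    element = c(rep(g$element, counts), if (n_ch) rep(c("C", "H"), n_ch)),
    stringsAsFactors = FALSE)
  atoms$mass <- .elements$mass[match(atoms$element, .elements$element)]

  water_res <- unique(g$resname[g$water])
  top <- topology(atoms, spec$n_lipids_per_leaflet,
                  lipid_residue_names = "CHP",
                  water_residue_names = if (length(water_res)) water_res
                  else DEFAULT_WATER_RESNAMES)

  zmu <- rep(g$z_mean, counts)
  zsd <- rep(g$z_sigma, counts)
  coords <- array(NA_real_, c(natom, 3, spec$n_frames))
  box <- matrix(NA_real_, spec$n_frames, 3)

  with_seed(spec$seed, {
    for (f in seq_len(spec$n_frames)) {
      A <- spec$area_mean +
        if (spec$area_var > 0) stats::rnorm(1, 0, sqrt(spec$area_var)) else 0
      if (A <= 0) stop("sampled box area <= 0; reduce area variance")
      L <- sqrt(A)
      box[f, ] <- c(L, L, spec$Lz)
      coords[seq_len(natom_g), 1, f] <- stats::runif(natom_g, 0, L)
      coords[seq_len(natom_g), 2, f] <- stats::runif(natom_g, 0, L)
      coords[seq_len(natom_g), 3, f] <- stats::rnorm(natom_g, zmu, zsd)
      if (n_ch) {
        ct <- sqrt((2 * spec$ch$S + 1) / 3)      # cos(theta) on the cone
        st <- sqrt(1 - ct^2)
        cx <- stats::runif(n_ch, 0, L)
        cy <- stats::runif(n_ch, 0, L)
        cz <- stats::rnorm(n_ch, 0, 5)
        phi <- stats::runif(n_ch, 0, 2 * pi)
        ci <- natom_g + 2L * seq_len(n_ch) - 1L
        hi <- ci + 1L
        coords[ci, , f] <- cbind(cx, cy, cz)
        coords[hi, , f] <- cbind(cx + spec$ch$bond * st * cos(phi),
                                 cy + spec$ch$bond * st * sin(phi),
                                 cz + spec$ch$bond * ct)
      }
    }
  })

  traj <- trajectory(top, coords, box, dt_ps = 1)
  ch_pairs <- if (n_ch) {
    ci <- natom_g + 2L * seq_len(n_ch) - 1L
    data.frame(label = "CS", c_index = ci, h_index = ci + 1L)
  } else NULL

  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    write_psf(top, file.path(write_dir, "system.psf"))
    write_pdb(traj, file.path(write_dir, "traj.pdb"))
    write_dcd(traj, file.path(write_dir, "traj.dcd"))
  }
  list(topology = top, trajectory = traj, ch_pairs = ch_pairs, spec = spec)
}

# ------------------------------------------------- Langevin window engine --

numderiv <- function(f, h = 1e-4) function(z) (f(z + h) - f(z - h)) / (2 * h)

#' Specify a synthetic permeation model
#'
#' Declares the ground-truth free-energy profile w(z) and diffusivity D(z)
#' that overdamped Langevin window simulations are generated from, together
#' with the umbrella layout.
#'
#' @param w function of z returning the PMF, kcal/mol.
#' @param D function of z returning the diffusivity, A^2/ps, or a scalar.
#' @param temperature_K temperature, K.
#' @param centers umbrella window centers, Angstrom.
#' @param k umbrella spring constant, kcal/(mol A^2).
#' @param n_steps steps per window.
#' @param dt integration time step, ps; must resolve the fastest relaxation
#'   time (dt <= tau_min / 10).
#' @param thin record every \code{thin}-th integration step (default 1), so
#'   stored samples are \code{thin * dt} apart and less correlated at fixed
#'   storage.
#' @param seed RNG seed.
#' @return object of class \code{PermeationModelSpec}.
#' @export
permeation_model_spec <- function(w, D, temperature_K = 298,
                                  centers = seq(-40, 40, by = 1), k = 2.5,
                                  n_steps = 1e5, dt = 0.02, thin = 1L,
                                  seed = 1L) {
  Dfun <- if (is.function(D)) D else function(z) rep_len(D, length(z))
  if (any(Dfun(centers) <= 0)) stop("D(z) must be > 0")
  if (k < 0) stop("spring constant must be >= 0 (0 = unbiased)")
  structure(list(w = w, D = Dfun, temperature_K = temperature_K,
                 centers = centers, k = k, n_steps = as.integer(n_steps),
                 dt = dt, thin = as.integer(thin), seed = seed),
            class = "PermeationModelSpec")
}

# overdamped Euler-Maruyama on total potential U(z) = w(z) + bias_i(z), with
# position-dependent D under the Ito convention (spurious drift dD/dz).
# Vectorized across windows: one vector step per time step.
.langevin_engine <- function(w, Dfun, centers, k, kT, n_steps, dt,
                             thin = 1L) {
  dw <- numderiv(w)
  dD <- numderiv(Dfun)
  z <- centers
  nw <- length(centers)
  out <- matrix(NA_real_, n_steps, nw)
  sq <- sqrt(2 * dt)
  for (s in seq_len(n_steps * thin)) {
    Dz <- Dfun(z)
    drift <- -Dz * (dw(z) + k * (z - centers)) / kT + dD(z)
    z <- z + drift * dt + sq * sqrt(Dz) * stats::rnorm(nw)
    if (s %% thin == 0L) out[s %/% thin, ] <- z
  }
  out
}

#' Generate umbrella-window and restrained time series by Langevin dynamics
#'
#' Simulates the declared model with overdamped Euler-Maruyama dynamics
#' (Ito convention, with the dD/dz spurious-drift term for
#' position-dependent diffusivity).  Validates that the time step resolves
#' the fastest local relaxation time tau_i = kB T / (D(c_i) (w''(c_i) + k)):
#' dt must be <= tau_min / 10.
#'
#' @param spec a \code{PermeationModelSpec}.
#' @param restraint_k spring constant of the stiff diffusivity restraints,
#'   kcal/(mol A^2) (default 20); set NULL to skip.
#' @param restraint_centers centers of the restrained series (default the
#'   umbrella centers).
#' @param restraint_steps steps per restrained series.
#' @param restraint_dt time step for the restrained series, ps (default the
#'   umbrella dt); the stiff restraint usually demands a smaller step.
#' @param write_dir if non-NULL, writes window files plus a manifest there.
#' @return list with \code{umbrella} (list of \code{UmbrellaWindow}, no
#'   equilibration discarded yet), \code{restrained} (list of
#'   \code{(center, k, dt, samples)}), and \code{spec}.
#' @export
gen_langevin_windows <- function(spec, restraint_k = 20,
                                 restraint_centers = NULL,
                                 restraint_steps = spec$n_steps,
                                 restraint_dt = NULL,
                                 write_dir = NULL) {
  stopifnot(inherits(spec, "PermeationModelSpec"))
  if (spec$n_steps < 1) stop("n_steps must be >= 1")
  kT <- .const$kB_kcal * spec$temperature_K

  d2w <- function(z, h = 1e-3)
    (spec$w(z + h) - 2 * spec$w(z) + spec$w(z - h)) / h^2
  check_dt <- function(dt, k_extra, centers, what) {
    stiff <- pmax(d2w(centers), 0) + k_extra
    tau_min <- min(kT / (spec$D(centers) * stiff))
    if (dt > tau_min / 10)
      stop(sprintf(
        "%s dt = %g ps does not resolve the fastest relaxation (tau_min = %.4g ps); need dt <= %.4g",
        what, dt, tau_min, tau_min / 10))
  }
  check_dt(spec$dt, spec$k, spec$centers, "umbrella")
  rc <- if (is.null(restraint_centers)) spec$centers else restraint_centers
  if (!is.null(restraint_k)) {
    if (is.null(restraint_dt)) restraint_dt <- spec$dt
    check_dt(restraint_dt, restraint_k, rc, "restrained-series")
  }

  res <- with_seed(spec$seed, {
    um <- .langevin_engine(spec$w, spec$D, spec$centers, spec$k, kT,
                           spec$n_steps, spec$dt, spec$thin)
    rs <- if (!is.null(restraint_k))
      .langevin_engine(spec$w, spec$D, rc, restraint_k, kT,
                       restraint_steps, restraint_dt)
    else NULL
    list(um = um, rs = rs, rc = rc)
  })

  umbrella <- lapply(seq_along(spec$centers), function(i)
    umbrella_window(spec$centers[i], spec$k, res$um[, i],
                    equilibration_fraction = 0, dt_ps = spec$dt * spec$thin))
  restrained <- if (!is.null(res$rs))
    lapply(seq_along(res$rc), function(i)
      list(center = res$rc[i], k = restraint_k, dt = restraint_dt,
           samples = res$rs[, i])) else NULL

  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("window_%03d.dat", seq_along(umbrella))
    for (i in seq_along(umbrella))
      write_umbrella_window(umbrella[[i]], file.path(write_dir, files[i]))
    writeLines(c("# umbrella window manifest", files),
               file.path(write_dir, "manifest.txt"))
  }
  list(umbrella = umbrella, restrained = restrained, spec = spec)
}

# -------------------------------------------------- lambda-coupled dataset -

#' Generate lambda-coupled harmonic-oscillator free-energy samples
#'
#' The coupled potential is U(x; lambda) = k(lambda) x^2 / 2 with
#' k(lambda) = k0 + (k1 - k0) lambda.  Each window is sampled exactly from
#' its Gaussian Boltzmann distribution; dU/dlambda = (k1 - k0) x^2 / 2 and
#' neighbor-stage energy differences dU = (k_next - k_this) x^2 / 2 are
#' emitted.  The analytic free energy is dG = (kB T / 2) ln(k1 / k0).
#'
#' @param k0,k1 endpoint spring constants, kcal/(mol A^2), > 0.
#' @param grid lambda grid (default 0 to 1 step 0.1, the conventional
#'   11-window layout).
#' @param temperature_K temperature, K.
#' @param n samples per window.
#' @param seed RNG seed.
#' @param component component label for the TI windows.
#' @param write_dir if non-NULL, writes one file per window/stage plus a
#'   manifest recording the analytic dG.
#' @return list with \code{ti_windows} (list of \code{LambdaWindow}),
#'   \code{stages} (list of \code{(du_forward, du_reverse)}),
#'   \code{dG_exact} (kcal/mol), \code{temperature_K}.
#' @export
gen_lambda_dataset <- function(k0, k1, grid = seq(0, 1, by = 0.1),
                               temperature_K = 298, n = 1e4, seed = 1L,
                               component = "disp", write_dir = NULL) {
  if (k0 <= 0 || k1 <= 0) stop("spring constants must be > 0")
  if (is.unsorted(grid, strictly = TRUE)) stop("lambda grid must be sorted")
  kT <- .const$kB_kcal * temperature_K
  klam <- k0 + (k1 - k0) * grid
  dG_exact <- kT / 2 * log(k1 / k0)

  xs <- with_seed(seed, lapply(klam, function(kl)
    stats::rnorm(n, 0, sqrt(kT / kl))))

  ti_windows <- lapply(seq_along(grid), function(i)
    lambda_window(grid[i], component, (k1 - k0) / 2 * xs[[i]]^2,
                  temperature_K))
  ng <- length(grid)
  stages <- lapply(seq_len(ng - 1), function(i) list(
    du_forward = (klam[i + 1] - klam[i]) / 2 * xs[[i]]^2,
    du_reverse = (klam[i] - klam[i + 1]) / 2 * xs[[i + 1]]^2))

  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    man <- c(sprintf("# analytic dG = %.10g kcal/mol (kT/2 ln(k1/k0))",
                     dG_exact))
    for (i in seq_along(grid)) {
      fn <- sprintf("ti_lambda_%04.2f.dat", grid[i])
      write_lambda_file(ti_windows[[i]]$dudl, file.path(write_dir, fn),
                        grid[i], component, temperature_K, "dudl")
      man <- c(man, fn)
    }
    for (i in seq_along(stages)) {
      fn <- sprintf("fep_stage_%02d_fwd.dat", i)
      write_lambda_file(stages[[i]]$du_forward, file.path(write_dir, fn),
                        grid[i], component, temperature_K, "du_forward")
      fr <- sprintf("fep_stage_%02d_rev.dat", i)
      write_lambda_file(stages[[i]]$du_reverse, file.path(write_dir, fr),
                        grid[i + 1], component, temperature_K, "du_reverse")
      man <- c(man, fn, fr)
    }
    writeLines(man, file.path(write_dir, "manifest.txt"))
  }
  list(ti_windows = ti_windows, stages = stages, dG_exact = dG_exact,
       temperature_K = temperature_K)
}

#' Exact discretization of an Ornstein-Uhlenbeck process
#'
#' Generates a stationary OU series with variance \code{sigma2} and
#' correlation time \code{tau} at sampling interval \code{dt} using the
#' exact update z' = mu + (z - mu) rho + sigma sqrt(1 - rho^2) xi,
#' rho = exp(-dt/tau).  This is the reference process for the restrained
#' diffusivity estimator: a harmonic restraint k at temperature T with
#' diffusivity D corresponds to sigma2 = kB T / k and tau = sigma2 / D.
#'
#' @param n number of samples.
#' @param sigma2 stationary variance, A^2.
#' @param tau correlation time, ps.
#' @param dt sampling interval, ps.
#' @param mu mean position, Angstrom.
#' @param seed RNG seed.
#' @return numeric vector of length \code{n}.
#' @export
gen_ou_series <- function(n, sigma2, tau, dt, mu = 0, seed = 1L) {
  if (sigma2 <= 0 || tau <= 0 || dt <= 0) stop("sigma2, tau, dt must be > 0")
  rho <- exp(-dt / tau)
  s <- sqrt(sigma2 * (1 - rho^2))
  with_seed(seed, {
    z <- numeric(n)
    z[1] <- mu + stats::rnorm(1, 0, sqrt(sigma2))
    innov <- stats::rnorm(n - 1, 0, s)
    for (i in 2:n) z[i] <- mu + (z[i - 1] - mu) * rho + innov[i - 1]
    z
  })
}
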