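# Transmembrane density profiles, scattering form factors, and the
# membrane dipole potential.

#' Transmembrane density profile
#'
#' Histograms per-atom weights along the membrane normal (z), frame by frame,
#' and normalizes by the slab volume <L_X L_Y> * dz.  The weight is chosen by
#' \code{kind}: electron counts (electrons/A^3), partial charges (e/A^3), or
#' neutron scattering lengths (fm/A^3), all taken from a
#' \code{\link{assign_weights}} result.
#'
#' Normalization uses the mean lateral area over the analyzed frames, so the
#' conservation identity sum(value) * dz * <L_X L_Y> = mean total weight per
#' frame holds exactly.
#'
#' @param traj a recentered \code{Trajectory} (see
#'   \code{\link{recenter_frames}}).
#' @param weights a \code{ScatteringWeights}.
#' @param kind \code{"electron"}, \code{"charge"} or \code{"nsl"}.
#' @param bin_width bin width along z, Angstrom (default 0.2).
#' @param selection optional 1-based atom indices to include (default all).
#' @param symmetrize average bins at +z and -z (symmetric-bilayer view).
#' @return object of class \code{DensityProfile}: list with \code{z} (bin
#'   centers), \code{value}, \code{kind}, \code{bin_width}, \code{n_frames},
#'   \code{mean_area}.
#' @export
density_profile <- function(traj, weights, kind = c("electron", "charge", "nsl"),
                            bin_width = 0.2, selection = NULL,
                            symmetrize = FALSE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(weights, "ScatteringWeights"))
  kind <- match.arg(kind)
  if (bin_width <= 0) stop("bin_width must be > 0")
  w_all <- switch(kind,
                  electron = weights$electron_count,
                  charge   = weights$charge,
                  nsl      = weights$nsl_fm)
  if (length(w_all) != nrow(traj$topology$atoms))
    stop("weights do not match the trajectory's topology")
  if (is.null(selection)) selection <- seq_along(w_all)
  w <- w_all[selection]

  Lz_max <- max(traj$box[, 3])
  half <- bin_width * ceiling(Lz_max / 2 / bin_width)
  edges <- seq(-half, half, by = bin_width)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    Lz <- traj$box[k, 3]
    z <- traj$coords[selection, 3, k]
    z <- (z + Lz / 2) %% Lz - Lz / 2          # wrap before binning
    bin <- findInterval(z, edges, rightmost.closed = FALSE)
    if (any(bin < 1L | bin > nb))
      stop("internal error: wrapped coordinate outside the binning range")
    sums <- rowsum(as.numeric(w), bin)           # one row per occupied bin
    at <- as.integer(rownames(sums))
    acc[at] <- acc[at] + sums[, 1]
  }
  mean_area <- mean(traj$box[, 1] * traj$box[, 2])
  value <- acc / (nf * mean_area * bin_width)
  if (symmetrize) value <- (value + rev(value)) / 2
  structure(list(z = (edges[-1] + edges[-length(edges)]) / 2,
                 value = value, kind = kind, bin_width = bin_width,
                 n_frames = nf, mean_area = mean_area,
                 units = switch(kind, electron = "electrons/A^3",
                                charge = "e/A^3", nsl = "fm/A^3")),
            class = "DensityProfile")
}

#' Construct a density profile from explicit values
#'
#' For analytic or externally computed profiles on a uniform z grid.
#'
#' @param z bin centers, Angstrom (uniform spacing).
#' @param value profile values.
#' @param kind weight kind tag.
#' @param mean_area mean lateral area, Angstrom^2 (optional).
#' @return a \code{DensityProfile}.
#' @export
as_density_profile <- function(z, value,
                               kind = c("electron", "charge", "nsl"),
                               mean_area = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(z) == length(value), length(z) >= 2)
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-9 * abs(dz[1]))
    stop("z grid must be uniform")
  structure(list(z = z, value = value, kind = kind, bin_width = dz[1],
                 n_frames = NA_integer_, mean_area = mean_area,
                 units = switch(kind, electron = "electrons/A^3",
                                charge = "e/A^3", nsl = "fm/A^3")),
            class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile (%s): %d bins, dz = %g A, z in [%g, %g]\n",
              x$kind, length(x$z), x$bin_width, min(x$z), max(x$z)))
  invisible(x)
}

#' Symmetrize a density profile about z = 0
#' @param profile a \code{DensityProfile} on a grid symmetric about 0.
#' @return the symmetrized \code{DensityProfile}.
#' @export
symmetrize_profile <- function(profile) {
  stopifnot(inherits(profile, "DensityProfile"))
  if (abs(profile$z[1] + profile$z[length(profile$z)]) > 1e-6)
    stop("profile grid is not symmetric about z = 0")
  profile$value <- (profile$value + rev(profile$value)) / 2
  profile
}

#' Estimate the bulk solvent density of a profile
#'
#' Mean profile value over the bulk region \code{|z| >= bulk_zmin}.
#'
#' @param profile a \code{DensityProfile}.
#' @param bulk_zmin start of the bulk-water region, Angstrom (default 30).
#' @return scalar bulk density in the profile's units.
#' @export
bulk_density <- function(profile, bulk_zmin = 30) {
  sel <- abs(profile$z) >= bulk_zmin
  if (!any(sel)) stop("no bins with |z| >= ", bulk_zmin, " in the profile")
  mean(profile$value[sel])
}

#' Scattering form factor of a density profile
#'
#' One-dimensional Fourier transform of the contrast against the bulk
#' solvent: |F(q)| = | integral [rho(z) - rho_w] (cos(qz) + i sin(qz)) dz |,
#' evaluated by trapezoid quadrature over the profile's z range.
#'
#' @param profile a \code{DensityProfile} (electron -> X-ray, nsl -> neutron).
#' @param rho_w bulk solvent density in the profile's units; default
#'   estimated from the \code{|z| >= 30} region via \code{\link{bulk_density}}.
#' @param q_grid scattering vector grid, 1/Angstrom (default 0 to 1, step
#'   0.005).
#' @param symmetrize symmetrize the profile first (experimental curves assume
#'   a symmetric bilayer); default \code{TRUE}.
#' @return object of class \code{FormFactor}: list with \code{q}, \code{F}
#'   (modulus, e/A^2 or fm/A^2), \code{rho_w}, \code{kind}.
#' @export
form_factor <- function(profile, rho_w = NULL,
                        q_grid = seq(0, 1, by = 0.005), symmetrize = TRUE) {
  stopifnot(inherits(profile, "DensityProfile"))
  if (any(q_grid < 0)) stop("q_grid must be non-negative")
  if (is.null(rho_w)) rho_w <- bulk_density(profile)
  if (profile$kind == "electron" && rho_w < 0)
    stop("rho_w must be >= 0 for electron density")
  if (symmetrize &&
      abs(profile$z[1] + profile$z[length(profile$z)]) < 1e-6)
    profile <- symmetrize_profile(profile)
  z <- profile$z
  contrast <- profile$value - rho_w
  Fre <- vapply(q_grid, function(q) pracma::trapz(z, contrast * cos(q * z)),
                numeric(1))
  Fim <- vapply(q_grid, function(q) pracma::trapz(z, contrast * sin(q * z)),
                numeric(1))
  structure(list(q = q_grid, F = sqrt(Fre^2 + Fim^2),
                 F_re = Fre, F_im = Fim, rho_w = rho_w, kind = profile$kind),
            class = "FormFactor")
}

#' Neutron scattering form factor from a trajectory
#'
#' Convenience composition: NSLD profile of the trajectory with
#' D2O-substituted water hydrogens, then \code{\link{form_factor}}.
#'
#' @param traj a recentered \code{Trajectory}.
#' @param weights \code{ScatteringWeights} built with
#'   \code{d2o_substitution = TRUE}.
#' @param rho_w bulk D2O scattering length density, fm/A^3 (default from the
#'   profile's bulk region).
#' @param q_grid scattering vector grid, 1/Angstrom.
#' @param bin_width profile bin width, Angstrom.
#' @return a \code{FormFactor} (fm/A^2).
#' @export
nsld_form_factor <- function(traj, weights, rho_w = NULL,
                             q_grid = seq(0, 1, by = 0.005),
                             bin_width = 0.2) {
  prof <- density_profile(traj, weights, kind = "nsl", bin_width = bin_width)
  form_factor(prof, rho_w = rho_w, q_grid = q_grid)
}

#' Membrane dipole potential from a charge density profile
#'
#' Double cumulative integration of the charge density:
#' phi(z) - phi(z0) = -(1/eps0) int_z0^z int_z0^z' zeta(z'') dz'' dz',
#' with phi(z0) = 0 at a reference position z0 in bulk solution.  Both
#' integrals are trapezoid cumulative sums on the profile grid; output in
#' volts.
#'
#' @param charge_profile a \code{DensityProfile} of kind \code{"charge"}
#'   (e/A^3); must be net neutral.
#' @param z0 reference position, Angstrom; default the leftmost grid point.
#' @param detrend if \code{TRUE}, subtract the linear ramp that makes phi
#'   equal at both box edges (off by default).
#' @return object of class \code{PotentialProfile}: list with \code{z},
#'   \code{phi} (volts), \code{z0}.
#' @export
dipole_potential <- function(charge_profile, z0 = NULL, detrend = FALSE) {
  stopifnot(inherits(charge_profile, "DensityProfile"))
  if (charge_profile$kind != "charge")
    stop("dipole_potential needs a charge-kind profile")
  z <- charge_profile$z
  zeta <- charge_profile$value
  net_per_area <- pracma::trapz(z, zeta)              # e/A^2
  net <- if (is.finite(charge_profile$mean_area))
    net_per_area * charge_profile$mean_area else net_per_area
  if (abs(net) > 1e-6)
    stop(sprintf(
      "net charge %.3g e is non-zero; the potential would diverge", net))
  if (is.null(z0)) z0 <- z[1]
  i0 <- which.min(abs(z - z0))
  c1 <- pracma::cumtrapz(z, zeta)[, 1]                # e/A^2
  c1 <- c1 - c1[i0]
  c2 <- pracma::cumtrapz(z, c1)[, 1]                  # e/A
  c2 <- c2 - c2[i0]
  phi <- -c2 * .const$e_over_eps0_A                   # volts
  if (detrend) {
    ramp <- (phi[length(phi)] - phi[1]) *
      (z - z[1]) / (z[length(z)] - z[1])
    phi <- phi - ramp
    phi <- phi - phi[i0]
  }
  structure(list(z = z, phi = phi, z0 = z[i0]), class = "PotentialProfile")
}

#' Read an experimental form-factor table
#'
#' Two-column whitespace-separated text: q (1/Angstrom) and |F(q)|;
#' \code{#} comment lines are skipped.
#'
#' @param path table file.
#' @return data.frame with columns \code{q} and \code{F}.
#' @export
read_form_factor_table <- function(path) {
  if (!file.exists(path)) stop("form factor table not found: ", path)
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("q", "F"),
                         colClasses = "numeric")
  if (!nrow(d)) stop("empty form factor table: ", path)
  d
}

#' Compare a computed form factor with an experimental table
#'
#' Interpolates the computed |F| linearly onto the experimental q points of
#' the overlapping range, optionally restricted to \code{q_range} (e.g. the
#' reliable neutron window 0 < q < 0.2 1/Angstrom).  With
#' \code{scale = "free"}, a least-squares scalar k minimizing
#' sum (k |F_exp| - |F_sim|)^2 absorbs the arbitrary experimental scale;
#' \code{"fixed"} keeps k = 1.
#'
#' @param computed a \code{FormFactor}.
#' @param experimental data.frame with \code{q}, \code{F}, or a file path.
#' @param scale \code{"free"} or \code{"fixed"}.
#' @param q_range optional length-2 numeric restriction on q.
#' @return list with \code{k} (scale), \code{rms} (residual RMS in computed
#'   units), \code{n} points compared, \code{q_range} used.
#' @export
compare_form_factors <- function(computed, experimental,
                                 scale = c("free", "fixed"), q_range = NULL) {
  stopifnot(inherits(computed, "FormFactor"))
  scale <- match.arg(scale)
  if (is.character(experimental))
    experimental <- read_form_factor_table(experimental)
  q <- experimental$q
  keep <- q >= min(computed$q) & q <= max(computed$q)
  if (!is.null(q_range)) keep <- keep & q >= q_range[1] & q <= q_range[2]
  if (!any(keep)) stop("no overlapping q range between the two curves")
  qe <- q[keep]
  Fe <- experimental$F[keep]
  Fs <- stats::approx(computed$q, computed$F, xout = qe)$y
  k <- if (scale == "free") sum(Fe * Fs) / sum(Fe^2) else 1
  rms <- sqrt(mean((k * Fe - Fs)^2))
  list(k = k, rms = rms, n = length(qe), q_range = range(qe))
}

#' Write a profile or form factor as tab-separated text
#'
#' Comment header lines name the columns and units.
#'
#' @param x a \code{DensityProfile}, \code{PotentialProfile} or
#'   \code{FormFactor}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(x, path) {
  if (inherits(x, "DensityProfile")) {
    hdr <- sprintf("# z_A\tvalue_%s", gsub("/", "_per_", x$units))
    d <- data.frame(x$z, x$value)
  } else if (inherits(x, "PotentialProfile")) {
    hdr <- "# z_A\tphi_V"
    d <- data.frame(x$z, x$phi)
  } else if (inherits(x, "FormFactor")) {
    hdr <- "# q_invA\tF_abs"
    d <- data.frame(x$q, x$F)
  } else stop("unsupported object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
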