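# Umbrella-sampling PMF via WHAM, position-dependent diffusivity from the
# autocorrelation of a restrained coordinate, and the solubility-diffusion
# permeability integral.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Construct an umbrella-sampling window
#'
#' @param center restraint center z0, Angstrom.
#' @param k harmonic spring constant, kcal/(mol A^2); the bias is
#'   0.5 k (z - z0)^2.
#' @param samples sampled z positions, Angstrom (time order).
#' @param equilibration_fraction leading fraction of the samples discarded as
#'   equilibration (default 1/6, mirroring discarding 20 ns of a 120 ns
#'   window run).
#' @param dt_ps sampling interval, ps (metadata).
#' @return object of class \code{UmbrellaWindow}.
#' @export
umbrella_window <- function(center, k, samples,
                            equilibration_fraction = 1 / 6, dt_ps = NA_real_) {
  if (k < 0) stop("spring constant must be >= 0 (0 = unbiased window)")
  drop <- floor(length(samples) * equilibration_fraction)
  samples <- samples[seq.int(drop + 1L, length(samples))]
  if (length(samples) < 100)
    stop("fewer than 100 post-equilibration samples in window at z0 = ",
         center)
  structure(list(center = center, k = k, samples = samples,
                 equilibration_fraction = equilibration_fraction,
                 dt_ps = dt_ps),
            class = "UmbrellaWindow")
}

#' Potential of mean force from umbrella windows (WHAM)
#'
#' Standard 1-D weighted histogram analysis: the unbiased bin probability is
#' p_j = sum_i n_ij / sum_i N_i exp((f_i - b_i(z_j))/kB T) with the window
#' free energies f_i iterated to self-consistency
#' (f_i = -kB T ln sum_j p_j exp(-b_i(z_j)/kB T)) until the largest change in
#' any f_i is below \code{tolerance}.  The PMF is w(z) = -kB T ln p(z),
#' shifted per \code{offset}: mean zero over the bulk region
#' \code{|z| >= bulk_zmin} (default), minimum zero, or unshifted.
#'
#' Bins inside the covered range left empty by all windows are flagged and
#' carry \code{NA}.
#'
#' @param windows list of \code{UmbrellaWindow}s.
#' @param temperature_K temperature, K.
#' @param bin_width histogram bin width, Angstrom.
#' @param tolerance convergence threshold on the window free energies,
#'   kcal/mol.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final residual.
#' @param offset \code{"bulk"}, \code{"min"} or \code{"none"}.
#' @param bulk_zmin bulk region boundary for the \code{"bulk"} offset,
#'   Angstrom.
#' @return object of class \code{PMFProfile}: list with \code{z}, \code{w}
#'   (kcal/mol), \code{f} (window free energies), \code{iterations},
#'   \code{final_residual}, \code{temperature_K}.
#' @export
wham_pmf <- function(windows, temperature_K = 298, bin_width = 0.5,
                     tolerance = 1e-8, max_iter = 100000,
                     offset = c("bulk", "min", "none"), bulk_zmin = 35) {
  offset <- match.arg(offset)
  if (!length(windows)) stop("no umbrella windows supplied")
  if (temperature_K <= 0) stop("temperature must be > 0")
  kT <- .const$kB_kcal * temperature_K
  centers <- vapply(windows, `[[`, numeric(1), "center")
  kk <- vapply(windows, `[[`, numeric(1), "k")
  cgap <- diff(sort(centers))
  if (length(cgap) && max(cgap) > 5 * max(bin_width, 1))
    warning("window centers leave a gap of ", signif(max(cgap), 3),
            " A; the PMF may be unreliable across it")

  zr <- range(unlist(lapply(windows, `[[`, "samples")))
  edges <- seq(floor(zr[1] / bin_width) * bin_width,
               ceiling(zr[2] / bin_width) * bin_width, by = bin_width)
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(zc)
  nw <- length(windows)

  n_ij <- vapply(windows, function(w) {
    b <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    tabulate(b, nbins = nb)
  }, numeric(nb))                                      # nb x nw
  N_i <- colSums(n_ij)
  n_j <- rowSums(n_ij)
  occupied <- n_j > 0
  inner <- range(which(occupied))
  holes <- which(!occupied)
  holes <- holes[holes > inner[1] & holes < inner[2]]

  bias <- 0.5 * sweep(outer(zc, centers, `-`)^2, 2, kk, `*`)   # nb x nw
  u <- bias / kT                                # reduced biases, nb x nw
  log_nj <- ifelse(occupied, log(n_j), -Inf)
  lse_rows <- function(M) {
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  # one step of the self-consistency map: f -> f'(f)
  sc_step <- function(f) {
    den <- lse_rows(sweep(-u, 2, log(N_i) + f / kT, `+`))
    log_p <- log_nj - den
    f_new <- -kT * apply(sweep(-u, 1, log_p, `+`), 2, logsumexp)
    list(f = f_new - f_new[1], log_p = log_p)
  }

  # The fixed point is the minimum of the (convex) unbinned-likelihood
  # objective A(g) = sum_j n_j log sum_i N_i exp(g_i - u_ij) - sum_i N_i g_i
  # (g = f/kT, gauge g_1 = 0); solve it by L-BFGS with analytic gradient,
  # then polish with the self-consistency map until the stated tolerance
  # on max |f' - f| is met.
  f <- numeric(nw)
  opt_iter <- 0L
  if (nw > 1) {
    occ <- occupied
    Afun <- function(h) {
      g <- c(0, h)
      den <- lse_rows(sweep(-u[occ, , drop = FALSE], 2, log(N_i) + g, `+`))
      sum(n_j[occ] * den) - sum(N_i * g)
    }
    Agrad <- function(h) {
      g <- c(0, h)
      L <- sweep(-u[occ, , drop = FALSE], 2, log(N_i) + g, `+`)
      den <- lse_rows(L)
      grad <- colSums(n_j[occ] * exp(L - den)) - N_i
      grad[-1]
    }
    opt <- stats::optim(numeric(nw - 1), Afun, Agrad, method = "L-BFGS-B",
                        control = list(maxit = 1000, factr = 10))
    f <- c(0, opt$par) * kT
    opt_iter <- opt$counts[["function"]]
  }
  iter <- 0L
  repeat {
    st <- sc_step(f)
    resid <- max(abs(st$f - f))
    f <- st$f
    log_p <- st$log_p
    iter <- iter + 1L
    if (resid < tolerance) break
    if (iter >= max_iter)
      stop(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
        max_iter, resid))
  }
  w <- -kT * log_p
  w[!occupied] <- NA_real_
  shift <- switch(offset,
                  bulk = {
                    sel <- abs(zc) >= bulk_zmin & occupied
                    if (!any(sel)) {
                      warning("no occupied bins with |z| >= ", bulk_zmin,
                              "; falling back to minimum-zero offset")
                      min(w, na.rm = TRUE)
                    } else mean(w[sel])
                  },
                  min = min(w, na.rm = TRUE),
                  none = 0)
  w <- w - shift
  structure(list(z = zc, w = w, f = f, iterations = iter,
                 optim_evals = opt_iter,
                 final_residual = resid, temperature_K = temperature_K,
                 bin_width = bin_width, offset = offset,
                 empty_interior_bins = zc[holes]),
            class = "PMFProfile")
}

#' @export
print.PMFProfile <- function(x, ...) {
  cat(sprintf(
    "PMFProfile: %d bins, z in [%g, %g] A, max w = %.2f kcal/mol (%d WHAM iterations)\n",
    length(x$z), min(x$z), max(x$z), max(x$w, na.rm = TRUE), x$iterations))
  invisible(x)
}

#' Local diffusivity from a harmonically restrained time series
#'
#' Generalized-Langevin (Hummer) relation for a coordinate restrained at one
#' position: D = <dz^2>^2 / integral_0^inf <dz(0) dz(t)> dt.  The position
#' autocovariance is computed by FFT; its time integral is taken by trapezoid
#' up to the first lag where the ACF falls below exp(-2) of its zero-time
#' value, plus an exponential-tail correction whose decay time is fitted over
#' the last e-fold of the kept portion.
#'
#' @param series restrained position samples, Angstrom (stationary).
#' @param dt sampling interval, ps.
#' @param k,temperature_K restraint spring constant (kcal/(mol A^2)) and
#'   temperature; optional, used only to cross-check the sampled variance
#'   against kB T / k.
#' @param tail_fit use the exponential-tail correction (default) or integrate
#'   a pure exponential fitted to the ACF instead (\code{"exp_fit"}).
#' @return list with \code{D_A2ps}, \code{D_cm2s} (1 A^2/ps = 1e-4 cm^2/s),
#'   \code{variance}, \code{tau_ps} (integrated correlation time),
#'   \code{cutoff_lag}.
#' @export
diffusivity_gle <- function(series, dt, k = NULL, temperature_K = NULL,
                            tail_fit = c("cutoff_tail", "exp_fit")) {
  tail_fit <- match.arg(tail_fit)
  n <- length(series)
  if (n < 1000) stop("series too short for an ACF-based estimate")
  if (dt <= 0) stop("dt must be > 0")
  dz <- series - mean(series)
  v <- mean(dz^2)
  if (v == 0) stop("non-dissipative series: zero variance")

  # unbiased autocovariance via FFT with zero padding
  m <- 2^ceiling(log2(2 * n))
  ft <- stats::fft(c(dz, rep(0, m - n)))
  # raw linear correlation sums (zero padding kills the circular wrap);
  # R's inverse fft is unnormalized, hence the 1/m
  ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE))[1:n] / m
  ac <- ac / (n - seq_len(n) + 1)              # unbiased: divide by n - lag

  c0 <- ac[1]
  below <- which(ac < exp(-2) * c0)
  if (!length(below)) {
    warning("ACF never decays below exp(-2) of its initial value; ",
            "integrating the full series")
    ic <- n %/% 2
  } else ic <- below[1]
  if (ic <= 5)
    warning("correlation time under-resolved: ACF decays within ", ic,
            " samples; decrease dt")

  tgrid <- (seq_len(ic) - 1) * dt
  if (tail_fit == "exp_fit") {
    # pure exponential fit over the kept portion
    pos <- ac[1:ic] > 0
    fit <- stats::lm(log(ac[1:ic][pos]) ~ tgrid[pos])
    tau <- -1 / stats::coef(fit)[2]
    integral <- c0 * tau
  } else {
    integral <- pracma::trapz(tgrid, ac[1:ic])
    # exponential tail from a fit over the last e-fold (C between e^-1 and
    # e^-2 of C0)
    sel <- which(ac[1:ic] <= exp(-1) * c0 & ac[1:ic] > 0)
    if (length(sel) >= 3) {
      fit <- stats::lm(log(ac[sel]) ~ tgrid[sel])
      slope <- stats::coef(fit)[2]
      if (is.finite(slope) && slope < 0)
        integral <- integral + ac[ic] * (-1 / slope)
    }
  }
  if (!is.finite(integral) || integral <= 0)
    stop("non-dissipative series: ACF integral <= 0")

  if (!is.null(k) && !is.null(temperature_K)) {
    v_exp <- .const$kB_kcal * temperature_K / k
    if (abs(v / v_exp - 1) > 0.25)
      warning(sprintf(
        "sampled variance %.4g A^2 deviates >25%% from kB T / k = %.4g A^2",
        v, v_exp))
  }
  D <- v^2 / integral
  list(D_A2ps = D, D_cm2s = D * 1e-4, variance = v, tau_ps = integral / v,
       cutoff_lag = ic)
}

#' Construct a diffusivity profile
#'
#' @param z positions, Angstrom.
#' @param D diffusivities (> 0).
#' @param units \code{"A2ps"} or \code{"cm2s"}; stored internally as A^2/ps.
#' @return object of class \code{DiffusivityProfile}.
#' @export
diffusivity_profile <- function(z, D, units = c("A2ps", "cm2s")) {
  units <- match.arg(units)
  if (any(D <= 0)) stop("diffusivities must be > 0 everywhere")
  if (units == "cm2s") D <- D * 1e4
  structure(list(z = z, D_A2ps = D), class = "DiffusivityProfile")
}

#' Membrane permeability from the inhomogeneous solubility-diffusion model
#'
#' 1/P_m = integral_{-L/2}^{L/2} exp(w(z)/kB T) / D(z) dz, by trapezoid
#' quadrature on the PMF grid with the diffusivity profile interpolated
#' linearly onto it.
#'
#' @param pmf a \code{PMFProfile} (w in kcal/mol).
#' @param diffusivity a \code{DiffusivityProfile}, or a scalar constant
#'   diffusivity in cm^2/s.
#' @param temperature_K temperature, K (default the PMF's).
#' @param bounds integration bounds \code{c(-L/2, L/2)} in Angstrom; default
#'   the PMF's occupied range.
#' @return object of class \code{PermeabilityResult}: list with \code{P_m}
#'   (cm/s), \code{resistivity} (1/P_m, s/cm), \code{bounds},
#'   \code{temperature_K}, and the resistivity \code{integrand} profile
#'   (s/cm^2 per cm).
#' @export
permeability_sd <- function(pmf, diffusivity, temperature_K = NULL,
                            bounds = NULL) {
  stopifnot(inherits(pmf, "PMFProfile"))
  if (is.null(temperature_K)) temperature_K <- pmf$temperature_K
  kT <- .const$kB_kcal * temperature_K
  ok <- is.finite(pmf$w)
  z <- pmf$z[ok]
  w <- pmf$w[ok]
  if (is.null(bounds)) bounds <- range(z)
  sel <- z >= bounds[1] & z <= bounds[2]
  z <- z[sel]; w <- w[sel]
  if (length(z) < 2) stop("PMF does not cover the integration bounds")
  if (any(!is.finite(w)))
    stop("PMF has empty bins inside the integration bounds")
  if (max(abs(w[c(1, length(w))])) > 0.5)
    warning("w(z) is non-zero at both integration bounds; bulk not reached")

  D_cm2s <- if (inherits(diffusivity, "DiffusivityProfile")) {
    d <- stats::approx(diffusivity$z, diffusivity$D_A2ps, xout = z)$y * 1e-4
    if (anyNA(d)) stop("diffusivity profile does not cover the PMF grid")
    d
  } else rep(as.numeric(diffusivity), length(z))
  if (any(D_cm2s <= 0)) stop("diffusivity must be > 0 on the whole grid")

  integrand <- exp(w / kT) / D_cm2s            # s/cm^2
  R <- pracma::trapz(z * 1e-8, integrand)      # s/cm
  structure(list(P_m = 1 / R, resistivity = R, bounds = bounds,
                 temperature_K = temperature_K,
                 integrand = data.frame(z = z, r = integrand)),
            class = "PermeabilityResult")
}

#' @export
print.PermeabilityResult <- function(x, ...) {
  cat(sprintf("P_m = %.3e cm/s over z in [%g, %g] A at %g K\n",
              x$P_m, x$bounds[1], x$bounds[2], x$temperature_K))
  invisible(x)
}

# ------------------------------------------------------- window file I/O ---

#' Write an umbrella window file
#'
#' Header lines \code{# center=... k=... dt=...} followed by one sampled z
#' per line.
#'
#' @param window an \code{UmbrellaWindow}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "UmbrellaWindow"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# center=%.6g k=%.6g dt=%.6g",
                     window$center, window$k, window$dt_ps), con)
  writeLines(sprintf("%.8g", window$samples), con)
  invisible(path)
}

#' Read an umbrella window file
#'
#' @param path window file written by \code{\link{write_umbrella_window}}
#'   (or any file with the same header convention).
#' @param equilibration_fraction leading fraction to discard; the samples in
#'   a file written by this package are already post-equilibration, so the
#'   default is 0.
#' @return an \code{UmbrellaWindow}.
#' @export
read_umbrella_window <- function(path, equilibration_fraction = 0) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-+0-9.eE]+"), hdr))
    m <- m[nzchar(m)]
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "="), "", m[1]))
  }
  center <- get("center"); k <- get("k"); dt <- get("dt")
  if (is.na(center) || is.na(k))
    stop("window file lacks '# center=... k=...' header: ", path)
  samples <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  umbrella_window(center, k, samples,
                  equilibration_fraction = equilibration_fraction,
                  dt_ps = dt)
}

#' Read a set of umbrella windows from a manifest
#'
#' The manifest lists one window file path per line (relative paths resolved
#' against the manifest's directory); \code{#} comments allowed.
#'
#' @param manifest manifest file.
#' @param equilibration_fraction passed to \code{\link{read_umbrella_window}}.
#' @return list of \code{UmbrellaWindow}s.
#' @export
read_umbrella_set <- function(manifest, equilibration_fraction = 0) {
  lines <- readLines(manifest, warn = FALSE)
  lines <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  base <- dirname(manifest)
  paths <- ifelse(file.exists(lines), lines, file.path(base, lines))
  lapply(paths, read_umbrella_window,
         equilibration_fraction = equilibration_fraction)
}
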