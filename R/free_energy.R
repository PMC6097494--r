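# Staged TI/FEP free-energy bookkeeping: thermodynamic integration over a
# lambda grid, free-energy perturbation (exponential averaging / Bennett),
# WCA component assembly, and water->hexadecane transfer energies.

#' Construct a lambda window of dU/dlambda samples (TI)
#'
#' @param lambda coupling parameter in [0, 1].
#' @param component \code{"elec"}, \code{"disp"} or \code{"rep"} (the
#'   electrostatic scaling and the Weeks-Chandler-Andersen split of the
#'   Lennard-Jones term).
#' @param dudl samples of dU/dlambda, kcal/mol (>= 100).
#' @param temperature_K temperature, K.
#' @return object of class \code{LambdaWindow}.
#' @export
lambda_window <- function(lambda, component = c("elec", "disp", "rep"),
                          dudl, temperature_K = 298) {
  component <- match.arg(component)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (length(dudl) < 100) stop("need >= 100 samples per lambda window")
  if (any(!is.finite(dudl))) stop("non-finite dU/dlambda sample")
  structure(list(lambda = lambda, component = component, dudl = dudl,
                 temperature_K = temperature_K),
            class = "LambdaWindow")
}

#' Thermodynamic integration over a lambda grid
#'
#' Trapezoid quadrature of the window means <dU/dlambda> over lambda.  The
#' uncertainty combines the block-averaged standard error of each window mean
#' through the quadrature weights in quadrature.
#'
#' @param windows list of \code{LambdaWindow}s of one component, any order.
#' @return list with \code{dG} (kcal/mol), \code{se}, \code{component},
#'   per-window \code{means}.
#' @export
ti_integrate <- function(windows) {
  if (length(windows) < 2) stop("TI needs at least 2 lambda windows")
  comp <- unique(vapply(windows, `[[`, character(1), "component"))
  if (length(comp) != 1)
    stop("all windows must belong to one component; got: ",
         paste(comp, collapse = ", "))
  lam <- vapply(windows, `[[`, numeric(1), "lambda")
  if (anyDuplicated(lam)) stop("duplicate lambda values")
  o <- order(lam)
  lam <- lam[o]; windows <- windows[o]
  mu <- vapply(windows, function(w) mean(w$dudl), numeric(1))
  se <- vapply(windows, function(w)
    tryCatch(block_average_se(w$dudl)$se, error = function(e) NA_real_),
    numeric(1))
  n <- length(lam)
  wt <- c(diff(lam)[1] / 2,
          if (n > 2) (lam[3:n] - lam[1:(n - 2)]) / 2 else NULL,
          diff(lam)[n - 1] / 2)
  list(dG = sum(wt * mu), se = sqrt(sum((wt * se)^2)), component = comp,
       means = data.frame(lambda = lam, mean_dudl = mu, se = se))
}

# Fermi function, numerically safe for large |t|
.fermi <- function(t) 1 / (1 + exp(pmin(t, 700)))

# Bennett acceptance ratio: forward works wf = U1-U0 sampled in state 0,
# reverse works wr = U0-U1 sampled in state 1.  Root of the standard
# implicit equation in dG.
.bar_dg <- function(wf, wr, kT) {
  M <- log(length(wf) / length(wr))
  g <- function(dG)
    sum(.fermi((wf - dG) / kT + M)) - sum(.fermi((wr + dG) / kT - M))
  gf <- -kT * (logsumexp(-wf / kT) - log(length(wf)))     # forward EXP
  gr <- kT * (logsumexp(-wr / kT) - log(length(wr)))      # reverse EXP
  lo <- min(gf, gr) - 10 * kT
  hi <- max(gf, gr) + 10 * kT
  while (g(lo) * g(hi) > 0 && hi - lo < 1e6) {
    lo <- lo - 10 * kT; hi <- hi + 10 * kT
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Free energy from staged perturbation samples
#'
#' Each stage boundary carries forward energy differences
#' dU = U_next - U_this sampled in this stage, and optionally reverse
#' differences dU = U_this - U_next sampled in the next stage.  Two-sided
#' stages are estimated by the binless self-consistent (Bennett acceptance
#' ratio) estimator; one-sided stages by exponential averaging
#' -kB T ln <exp(-dU/kB T)> via log-sum-exp.  Stage free energies are summed;
#' the uncertainty is a block bootstrap (fixed seed, 200 resamples) over the
#' sample series of every stage.
#'
#' @param stages list of stages, each a list with \code{du_forward}
#'   (required) and optional \code{du_reverse}, kcal/mol.
#' @param temperature_K temperature, K.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{dG} (kcal/mol), \code{se}, per-stage \code{dG_stage}.
#' @export
fep_stages <- function(stages, temperature_K = 298, n_boot = 200, seed = 42) {
  if (!length(stages)) stop("no stages supplied")
  kT <- .const$kB_kcal * temperature_K

  stage_dg <- function(fwd, rev) {
    if (any(!is.finite(fwd))) stop("non-finite dU sample: poor overlap")
    if (!is.null(rev)) .bar_dg(fwd, rev, kT)
    else {
      g <- -kT * (logsumexp(-fwd / kT) - log(length(fwd)))
      if (!is.finite(g)) stop("exponential averaging diverged: poor overlap")
      g
    }
  }
  dgs <- vapply(stages, function(s)
    stage_dg(s$du_forward, s$du_reverse), numeric(1))

  # block bootstrap over contiguous blocks of each stage's series
  boot_one <- function(x, nblk) {
    n <- length(x)
    b <- max(1L, n %/% nblk)
    starts <- seq(1L, n - b + 1L, by = b)
    pick <- sample(starts, length(starts), replace = TRUE)
    x[as.vector(outer(0:(b - 1L), pick, `+`))]
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  boots <- replicate(n_boot, sum(vapply(stages, function(s) {
    fwd <- boot_one(s$du_forward, 50L)
    rev <- if (!is.null(s$du_reverse)) boot_one(s$du_reverse, 50L) else NULL
    stage_dg(fwd, rev)
  }, numeric(1))))
  list(dG = sum(dgs), se = stats::sd(boots), dG_stage = dgs,
       temperature_K = temperature_K)
}

#' Assemble WCA free-energy components
#'
#' @param elec,disp,rep each a numeric \code{c(value, se)} pair, or a list
#'   with \code{dG}/\code{value} and \code{se} (as returned by
#'   \code{\link{ti_integrate}} / \code{\link{fep_stages}}).
#' @return object of class \code{FreeEnergyComponents}: data.frame with rows
#'   elec, disp, rep, total and columns \code{value}, \code{se}
#'   (uncertainties of the total combined in quadrature), kcal/mol.
#' @export
assemble_components <- function(elec, disp, rep) {
  pick <- function(x) {
    if (is.list(x)) {
      v <- if (!is.null(x$dG)) x$dG else x$value
      c(v, if (!is.null(x$se)) x$se else 0)
    } else c(x[1], if (length(x) > 1) x[2] else 0)
  }
  m <- rbind(elec = pick(elec), disp = pick(disp), rep = pick(rep))
  total <- c(sum(m[, 1]), sqrt(sum(m[, 2]^2)))
  out <- data.frame(component = c("elec", "disp", "rep", "total"),
                    value = c(m[, 1], total[1]),
                    se = c(m[, 2], total[2]),
                    stringsAsFactors = FALSE)
  class(out) <- c("FreeEnergyComponents", "data.frame")
  out
}

#' Tag a component set as the solvation result of one phase
#'
#' @param phase phase label, e.g. \code{"water"} or \code{"hexadecane"}.
#' @param components a \code{FreeEnergyComponents}.
#' @return object of class \code{SolvationResult}.
#' @export
solvation_result <- function(phase, components) {
  if (!nzchar(phase)) stop("phase label must be non-empty")
  stopifnot(inherits(components, "FreeEnergyComponents"))
  structure(list(phase = phase, components = components),
            class = "SolvationResult")
}

#' Transfer free energy between two solvation phases
#'
#' Component-wise difference dG_transfer = dG(destination) - dG(source):
#' for the water -> hexadecane transfer of one water molecule this is the
#' hexadecane solvation energy minus the excess chemical potential in water.
#' Uncertainties combine in quadrature.
#'
#' @param solv_to \code{SolvationResult} of the destination phase
#'   (e.g. hexadecane).
#' @param solv_from \code{SolvationResult} of the source phase (e.g. water).
#' @return a \code{FreeEnergyComponents} of the transfer.
#' @export
transfer_energy <- function(solv_to, solv_from) {
  stopifnot(inherits(solv_to, "SolvationResult"),
            inherits(solv_from, "SolvationResult"))
  a <- solv_to$components
  b <- solv_from$components
  if (!identical(a$component, b$component))
    stop("mismatched component sets between phases")
  part <- a$component != "total"
  assemble_components(
    elec = c(a$value[a$component == "elec"] - b$value[b$component == "elec"],
             sqrt(a$se[a$component == "elec"]^2 + b$se[b$component == "elec"]^2)),
    disp = c(a$value[a$component == "disp"] - b$value[b$component == "disp"],
             sqrt(a$se[a$component == "disp"]^2 + b$se[b$component == "disp"]^2)),
    rep  = c(a$value[a$component == "rep"] - b$value[b$component == "rep"],
             sqrt(a$se[a$component == "rep"]^2 + b$se[b$component == "rep"]^2)))
}

# ------------------------------------------------------------- file I/O ----

#' Write a lambda/stage sample file
#'
#' Header \code{# lambda=... component=... T=... kind=...}, one sample per
#' line (dU/dlambda for TI windows, dU for FEP stages).
#'
#' @param samples numeric samples, kcal/mol.
#' @param path output file.
#' @param lambda,component,temperature_K,kind header metadata; \code{kind} is
#'   \code{"dudl"}, \code{"du_forward"} or \code{"du_reverse"}.
#' @return \code{path}, invisibly.
#' @export
write_lambda_file <- function(samples, path, lambda, component,
                              temperature_K = 298, kind = "dudl") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda=%.6g component=%s T=%.6g kind=%s",
                     lambda, component, temperature_K, kind), con)
  writeLines(sprintf("%.10g", samples), con)
  invisible(path)
}

#' Read a lambda/stage sample file
#'
#' @param path file written by \code{\link{write_lambda_file}}.
#' @return list with \code{lambda}, \code{component}, \code{temperature_K},
#'   \code{kind}, \code{samples}.
#' @export
read_lambda_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)][1]
  if (is.na(hdr)) stop("lambda file lacks a header: ", path)
  getn <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-+0-9.eE]+"), hdr))
    if (!length(m)) NA_real_ else as.numeric(sub(paste0(key, "="), "", m))
  }
  gets <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[A-Za-z_]+"), hdr))
    if (!length(m)) NA_character_ else sub(paste0(key, "="), "", m)
  }
  samples <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  list(lambda = getn("lambda"), component = gets("component"),
       temperature_K = getn("T"), kind = gets("kind"), samples = samples)
}
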