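# Bilayer structural observables: area per lipid, area compressibility
# modulus, C-H order parameters, and block-averaged uncertainties.

#' Area per lipid from the lateral box dimensions
#'
#' The headgroup area is the mean lateral box area divided by the number of
#' lipids per leaflet: A_L = <L_X L_Y> / n_L.
#'
#' @param x a \code{Trajectory}, or a numeric matrix of box lengths with
#'   columns \code{(L_X, L_Y[, L_Z])}.
#' @param n_L lipids per leaflet; defaults to the topology's declared value
#'   when \code{x} is a \code{Trajectory}.
#' @param temperature_K simulation temperature (stored for the
#'   compressibility calculation).
#' @return object of class \code{AreaSeries}: list with per-frame \code{A_L}
#'   (Angstrom^2), \code{n_L}, \code{temperature_K} and the series
#'   \code{mean}.
#' @export
headgroup_area <- function(x, n_L = NULL, temperature_K = NA_real_) {
  if (inherits(x, "Trajectory")) {
    if (is.null(n_L)) n_L <- x$topology$n_lipids_per_leaflet
    box <- x$box
  } else {
    box <- as.matrix(x)
  }
  if (is.null(n_L) || n_L <= 0) stop("n_L must be a positive integer")
  A_L <- box[, 1] * box[, 2] / n_L
  if (any(A_L <= 0)) stop("non-positive box area encountered")
  structure(list(A_L = A_L, n_L = as.integer(n_L),
                 temperature_K = temperature_K, mean = mean(A_L)),
            class = "AreaSeries")
}

#' @export
print.AreaSeries <- function(x, ...) {
  cat(sprintf("AreaSeries: %d frames, <A_L> = %.2f A^2 (n_L = %d)\n",
              length(x$A_L), x$mean, x$n_L))
  invisible(x)
}

#' Area compressibility modulus from equilibrium area fluctuations
#'
#' K_A = k_B T <A_L> / (n_L <dA_L^2>), in dyn/cm (equivalently erg/cm^2).
#' The fluctuation <dA_L^2> is the biased (1/N) variance of the per-lipid
#' area series, per the thermodynamic fluctuation formula.  The uncertainty
#' is propagated from a block-averaged standard error of the squared
#' deviations.
#'
#' @param area_series an \code{AreaSeries} with a finite temperature.
#' @param temperature_K overrides the temperature stored in the series.
#' @return list with \code{K_A} (dyn/cm), \code{se}, \code{mean_area},
#'   \code{variance}, class \code{Compressibility}.
#' @export
area_compressibility <- function(area_series, temperature_K = NULL) {
  stopifnot(inherits(area_series, "AreaSeries"))
  T <- if (!is.null(temperature_K)) temperature_K else
    area_series$temperature_K
  if (!is.finite(T) || T <= 0)
    stop("a positive temperature (K) is required")
  A <- area_series$A_L
  if (length(A) < 2) stop("need at least 2 frames for a fluctuation")
  mA <- mean(A)
  vA <- mean((A - mA)^2)                       # 1/N variance
  if (vA == 0) stop("degenerate fluctuations: area series has zero variance")
  # kB T <A> / (nL var): [erg] * [1/A^2] -> erg/cm^2 via 1e16 A^2 / cm^2
  K_A <- .const$kB_erg * T * mA / (area_series$n_L * vA) * 1e16
  # relative error of the variance estimate, via block averaging of (A-mA)^2
  se <- tryCatch({
    b <- block_average_se((A - mA)^2)
    K_A * b$se / vA
  }, error = function(e) NA_real_)
  structure(list(K_A = K_A, se = se, mean_area = mA, variance = vA,
                 temperature_K = T, n_L = area_series$n_L),
            class = "Compressibility")
}

#' @export
print.Compressibility <- function(x, ...) {
  cat(sprintf("K_A = %.1f +/- %.1f dyn/cm (T = %g K, <A_L> = %.2f A^2)\n",
              x$K_A, x$se, x$temperature_K, x$mean_area))
  invisible(x)
}

#' C-H bond orientational order parameters
#'
#' For each carbon-hydrogen bond the order parameter is
#' S_CH = <(3 cos^2(theta) - 1)/2>, where theta is the angle between the
#' C-H vector and the membrane normal.  The signed average is retained
#' (headgroup order parameters are signed); the conventional deuterium
#' order parameter |S_CD| is its absolute value, averaged over the
#' hydrogens of each carbon.
#'
#' @param traj a \code{Trajectory}.
#' @param ch_pairs data.frame with columns \code{label} (site label, e.g.
#'   carbon name), \code{c_index}, \code{h_index} (1-based atom indices).
#' @param normal_axis unit 3-vector; default the z axis.
#' @return object of class \code{OrderParameterSet}: data.frame with one row
#'   per (label, pair): \code{label}, \code{S_signed}, \code{abs_S},
#'   \code{n_samples}; plus attribute \code{per_carbon} aggregating |S| over
#'   each label's hydrogens.
#' @export
order_parameters <- function(traj, ch_pairs, normal_axis = c(0, 0, 1)) {
  stopifnot(inherits(traj, "Trajectory"))
  need <- c("label", "c_index", "h_index")
  if (!all(need %in% names(ch_pairs)))
    stop("ch_pairs needs columns: ", paste(need, collapse = ", "))
  na <- nrow(traj$topology$atoms)
  if (any(ch_pairs$c_index < 1 | ch_pairs$c_index > na |
          ch_pairs$h_index < 1 | ch_pairs$h_index > na))
    stop("ch_pairs indices out of range")
  u <- normal_axis / sqrt(sum(normal_axis^2))
  nf <- n_frames(traj)
  np <- nrow(ch_pairs)
  s_sum <- numeric(np); s_n <- integer(np)
  for (k in seq_len(nf)) {
    d <- traj$coords[ch_pairs$h_index, , k] - traj$coords[ch_pairs$c_index, , k]
    d <- matrix(d, ncol = 3)
    len <- sqrt(rowSums(d^2))
    if (any(len == 0))
      stop("coincident C and H coordinates for pair ",
           which(len == 0)[1], " in frame ", k)
    ct <- (d %*% u) / len
    s_sum <- s_sum + (3 * ct^2 - 1) / 2
    s_n <- s_n + 1L
  }
  per_pair <- data.frame(label = ch_pairs$label,
                         S_signed = s_sum / s_n,
                         n_samples = s_n * 1L,
                         stringsAsFactors = FALSE)
  per_pair$abs_S <- abs(per_pair$S_signed)
  agg <- stats::aggregate(cbind(S_signed = per_pair$S_signed),
                          by = list(label = per_pair$label), FUN = mean)
  agg$abs_S_CD <- abs(agg$S_signed)
  structure(per_pair, per_carbon = agg,
            class = c("OrderParameterSet", "data.frame"))
}

#' Per-carbon aggregated |S_CD| of an order-parameter set
#' @param ops an \code{OrderParameterSet}.
#' @return data.frame with \code{label}, signed mean and \code{abs_S_CD}.
#' @export
per_carbon_order <- function(ops) attr(ops, "per_carbon")

#' Standard error of a correlated series by block averaging
#'
#' Splits the series into contiguous blocks and reports
#' sd(block means)/sqrt(n_blocks).  For correlated data the estimate grows
#' with block size and plateaus once blocks are longer than the correlation
#' time; the default block size is the plateau heuristic: the largest block
#' size that still leaves at least 10 blocks.
#'
#' @param series numeric vector.
#' @param block_sizes candidate block sizes; default a doubling ladder from
#'   1 to length(series)/4.
#' @return object of class \code{UncertaintyEstimate}: list with
#'   \code{mean}, \code{se}, \code{block_size}, and the full \code{curve}
#'   (data.frame block_size / se / n_blocks).
#' @export
block_average_se <- function(series, block_sizes = NULL) {
  n <- length(series)
  if (n < 4) stop("series too short for block averaging (need >= 4 points)")
  if (is.null(block_sizes)) {
    block_sizes <- 1L
    while (utils::tail(block_sizes, 1) * 2L <= n %/% 4L)
      block_sizes <- c(block_sizes, utils::tail(block_sizes, 1) * 2L)
  }
  block_sizes <- sort(unique(as.integer(block_sizes)))
  block_sizes <- block_sizes[block_sizes >= 1 & block_sizes <= n %/% 4L]
  if (!length(block_sizes))
    stop("series too short for the requested block sizes (need >= 4 blocks)")
  curve <- do.call(rbind, lapply(block_sizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    data.frame(block_size = b,
               se = stats::sd(bm) / sqrt(nb),
               n_blocks = nb)
  }))
  # plateau heuristic: largest block size with >= 10 blocks (fall back to
  # the largest available when the series is short)
  ok <- curve$n_blocks >= 10
  pick <- if (any(ok)) max(which(ok)) else nrow(curve)
  se <- curve$se[pick]
  if (is.na(se)) se <- 0                       # constant series
  structure(list(mean = mean(series), se = se,
                 block_size = curve$block_size[pick], curve = curve),
            class = "UncertaintyEstimate")
}

#' @export
print.UncertaintyEstimate <- function(x, ...) {
  cat(sprintf("mean = %g +/- %g (block size %d)\n",
              x$mean, x$se, x$block_size))
  invisible(x)
}
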