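#' Unwrap a phase series
#'
#' Standard 1D unwrap along time: jumps larger than pi between consecutive
#' samples are corrected by multiples of 2 pi.
#'
#' @param phase Numeric vector of wrapped phases in radians.
#' @return Unwrapped phase series.
#' @export
unwrap_phase <- function(phase) {
  d <- diff(phase)
  corr <- cumsum(-2 * pi * round(d / (2 * pi)))
  c(phase[1], phase[-1] + corr)
}

#' Unwrapped phase of one reduced-window cell
#'
#' `zeta(t) = U{arg I(t, r_jMA, phi_k, theta_l)}`, the carrier-scaled skin
#' displacement at that cell (a radial displacement `d` shifts the two-way
#' phase by `4 pi d / lambda0`).
#'
#' @param reduced A `reduced_window`.
#' @param k,l Azimuth and elevation cell indices.
#' @return Numeric vector of unwrapped phase in radians.
#' @export
unwrapped_phase <- function(reduced, k, l) {
  stopifnot(k >= 1, k <= dim(reduced$values)[2],
            l >= 1, l <= dim(reduced$values)[3])
  unwrap_phase(Arg(reduced$values[, k, l]))
}

# Normalized one-sided phase-spectrum magnitudes of a zeta series:
# |F(nu)| / sum |F| over positive frequencies up to Nyquist (DC excluded,
# since the absolute phase offset carries no displacement information).
# Returns list(freq, p) with sum(p) == 1.
phase_spectrum <- function(zeta, fs) {
  n <- length(zeta)
  f <- fft(zeta)
  half <- floor(n / 2)
  idx <- 2:(half + 1)
  mag <- Mod(f[idx])
  tot <- sum(mag)
  p <- if (tot > 0) mag / tot else rep(0, length(mag))
  list(freq = (idx - 1) * fs / n, p = p)
}

#' Per-cell indicator maps
#'
#' Computes the five per-cell features of a reduced window:
#' * `abar` - mean reflection amplitude at the selected range;
#' * `alpha1`, `alpha2` - mean and maximum normalized magnitude of the
#'   spectrum of the unwrapped phase within the respiration band
#'   `nu_rr = [0.09, 0.70] Hz` (the spectrum magnitudes are normalized to
#'   unit sum over positive frequencies, so both are unitless fractions
#'   with `alpha1 <= alpha2 <= 1`);
#' * `beta1`, `beta2` - standard deviation and 95th percentile (linear
#'   interpolation between order statistics) of the per-frame range of
#'   maximum amplitude `rMA`.
#'
#' Cells whose mean amplitude falls below the floor threshold (`a_ts_db`
#' decibels above the lower-quartile `abar` over all cells - a robust
#' stand-in for the background level that works even when bright cells
#' cover much of a tightly cropped map) are treated as noise-dominated:
#' each of their indicator values is substituted with the minimum value
#' attained over the passing cells.
#'
#' Each indicator is arranged both as an azimuth-elevation array and as an
#' elevation-distance array. For `abar` the latter is the azimuthal mean of
#' the full 3D mean-amplitude array; for the other indicators, each
#' azimuth-elevation value is assigned to the range bin `jMA` of its cell
#' and averaged over azimuth, with unassigned elevation-distance cells
#' taking the indicator's floor value.
#'
#' @param reduced A `reduced_window`.
#' @param a_ts_db Amplitude floor threshold in dB relative to the
#'   lower-quartile cell amplitude (default 10).
#' @param band Respiration band in Hz.
#' @return An object of class `indicator_maps` with `az_el` (list of five
#'   `n_phi x n_theta` matrices), `el_dist` (list of five
#'   `n_theta x n_r` matrices), the `pass` mask and the grid.
#' @export
compute_indicators <- function(reduced, a_ts_db = 10,
                               band = c(0.09, 0.70)) {
  stopifnot(inherits(reduced, "reduced_window"))
  np <- dim(reduced$values)[2]; nt <- dim(reduced$values)[3]
  nr <- reduced$grid$n_r
  fs <- reduced$frame_rate
  abar <- reduced$abar
  ats <- quantile(abar, 0.25, names = FALSE) * 10^(a_ts_db / 20)
  pass <- abar >= ats
  if (!any(pass)) stop("no cell passes the amplitude floor threshold")

  a1 <- a2 <- b1 <- b2 <- matrix(0, np, nt)
  for (k in seq_len(np)) for (l in seq_len(nt)) {
    zeta <- unwrap_phase(Arg(reduced$values[, k, l]))
    sp <- phase_spectrum(zeta, fs)
    inb <- sp$freq >= band[1] & sp$freq <= band[2]
    a1[k, l] <- mean(sp$p[inb])
    a2[k, l] <- max(sp$p[inb])
    b1[k, l] <- sd(reduced$rma[, k, l])
    b2[k, l] <- quantile(reduced$rma[, k, l], 0.95, type = 7, names = FALSE)
  }

  floor_sub <- function(m) {
    m[!pass] <- min(m[pass])
    m
  }
  az_el <- list(abar = floor_sub(abar), alpha1 = floor_sub(a1),
                alpha2 = floor_sub(a2), beta1 = floor_sub(b1),
                beta2 = floor_sub(b2))

  # elevation-distance arrangement
  r_axis <- reduced$grid$r_axis
  ed_abar <- t(apply(reduced$amean, c(1, 3), mean))  # nt x nr
  scatter_ed <- function(m) {
    out <- matrix(NA_real_, nt, nr)
    cnt <- matrix(0, nt, nr)
    acc <- matrix(0, nt, nr)
    for (k in seq_len(np)) for (l in seq_len(nt)) {
      j <- reduced$jma[k, l]
      acc[l, j] <- acc[l, j] + m[k, l]
      cnt[l, j] <- cnt[l, j] + 1
    }
    out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    out[cnt == 0] <- min(m)
    out
  }
  el_dist <- list(abar = ed_abar, alpha1 = scatter_ed(az_el$alpha1),
                  alpha2 = scatter_ed(az_el$alpha2),
                  beta1 = scatter_ed(az_el$beta1),
                  beta2 = scatter_ed(az_el$beta2))
  maps <- list(az_el = az_el, el_dist = el_dist, pass = pass,
               a_ts = ats, band = band, grid = reduced$grid)
  class(maps) <- "indicator_maps"
  maps
}

#' Stack indicator maps as normalized network inputs
#'
#' Each of the five channels of the azimuth-elevation and the
#' elevation-distance arrangement is independently shifted to zero mean and
#' scaled to unit standard deviation; constant channels map to all-zeros.
#'
#' @param maps An `indicator_maps` object.
#' @return List with `az_el` (`5 x n_phi x n_theta`) and `el_dist`
#'   (`5 x n_theta x n_r`) numeric arrays; channel order is
#'   (abar, alpha1, alpha2, beta1, beta2).
#' @export
to_heatmaps <- function(maps) {
  stopifnot(inherits(maps, "indicator_maps"))
  stack <- function(lst) {
    d <- dim(lst[[1]])
    out <- array(0, c(length(lst), d[1], d[2]))
    for (i in seq_along(lst)) {
      m <- lst[[i]]
      s <- sd(m)
      out[i, , ] <- if (s > 0) (m - mean(m)) / s else 0 * m
    }
    out
  }
  list(az_el = stack(maps$az_el), el_dist = stack(maps$el_dist))
}
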