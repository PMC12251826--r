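#' SFCW waveform description
#'
#' A stepped-frequency continuous-wave (SFCW) waveform is a comb of `L`
#' discrete tones centred on `f0` with step `delta_f`, so the occupied RF
#' bandwidth is `(L - 1) * delta_f`. One full sweep of the comb over all TX
#' elements constitutes a radar frame, repeated every `frame_interval`
#' seconds.
#'
#' Defaults correspond to a 60 GHz-band bedside monitor: `f0` = 65.5 GHz,
#' bandwidth 5.2 GHz over `L` = 75 tones and a 50 ms frame interval (20 Hz
#' frame rate).
#'
#' @param f0 Centre frequency in Hz.
#' @param bandwidth Occupied bandwidth `(L - 1) * delta_f` in Hz.
#' @param n_steps Number of tones `L`.
#' @param frame_interval Frame repetition interval in seconds.
#' @return An object of class `sfcw_waveform`.
#' @export
sfcw_waveform <- function(f0 = 65.5e9, bandwidth = 5.2e9, n_steps = 75,
                          frame_interval = 0.05) {
  stopifnot(f0 > 0, bandwidth > 0, n_steps >= 1, frame_interval > 0)
  delta_f <- if (n_steps > 1) bandwidth / (n_steps - 1) else bandwidth
  wf <- list(f0 = f0, bandwidth = bandwidth, L = as.integer(n_steps),
             delta_f = delta_f, frame_interval = frame_interval,
             lambda0 = C0 / f0, k0 = 2 * pi * f0 / C0)
  class(wf) <- "sfcw_waveform"
  wf
}

#' Instantaneous frequency grid of an SFCW waveform
#'
#' Tone `l` (1-based) sits at `f0 + (l - L/2) * delta_f`, so the comb is
#' affine in the tone index with slope `delta_f` and straddles the centre
#' frequency.
#'
#' @param waveform An [sfcw_waveform()].
#' @return Numeric vector of `L` frequencies in Hz, strictly increasing.
#' @export
frequency_grid <- function(waveform) {
  stopifnot(inherits(waveform, "sfcw_waveform"))
  l <- seq_len(waveform$L)
  waveform$f0 + (l - waveform$L / 2) * waveform$delta_f
}

#' L-shaped MIMO array geometry
#'
#' RX elements lie on the x-axis and TX elements on the z-axis, all in the
#' y = 0 plane, with uniform spacings `d_rx` and `d_tx`. Elements are centred
#' on the origin, which keeps the far-field phase approximation tight over
#' the small (about 4 cm) aperture.
#'
#' @param n_rx,n_tx Element counts `M` and `N`.
#' @param d_rx,d_tx Inter-element spacings in metres.
#' @return An object of class `array_geometry` with fields `rx_x` (M
#'   x-coordinates) and `tx_z` (N z-coordinates).
#' @export
array_geometry <- function(n_rx = 20, n_tx = 20, d_rx = 2.1e-3, d_tx = 2.1e-3) {
  stopifnot(n_rx >= 1, n_tx >= 1, d_rx > 0, d_tx > 0)
  geo <- list(M = as.integer(n_rx), N = as.integer(n_tx),
              d_rx = d_rx, d_tx = d_tx,
              rx_x = (seq_len(n_rx) - 1 - (n_rx - 1) / 2) * d_rx,
              tx_z = (seq_len(n_tx) - 1 - (n_tx - 1) / 2) * d_tx)
  class(geo) <- "array_geometry"
  geo
}

#' Derived radar parameters
#'
#' Closed-form quantities implied by a waveform: range resolution `c0 / B`,
#' unambiguous (maximum) range `c0 / (2 delta_f)`, and the maximum radial
#' velocity trackable without phase aliasing, `lambda0 / (4 frame_interval)`
#' (two-way propagation).
#'
#' @param waveform An [sfcw_waveform()].
#' @return Named list with `range_resolution` (m), `max_range` (m),
#'   `max_velocity` (m/s), `lambda0` (m), `delta_f` (Hz) and `frame_rate`
#'   (Hz).
#' @export
derived_parameters <- function(waveform) {
  stopifnot(inherits(waveform, "sfcw_waveform"))
  list(range_resolution = C0 / waveform$bandwidth,
       max_range = C0 / (2 * waveform$delta_f),
       max_velocity = waveform$lambda0 / (4 * waveform$frame_interval),
       lambda0 = waveform$lambda0,
       delta_f = waveform$delta_f,
       frame_rate = 1 / waveform$frame_interval)
}

#' Image reconstruction grid
#'
#' The 3D-FFT fast path evaluates the matched filter on a uniform grid in
#' range and in the direction cosines `u = cos(theta) sin(phi)` and
#' `v = sin(theta)`. Range bins are `r_p = p * c0 / (2 delta_f n_fft_range)`;
#' direction-cosine bins are `q * lambda0 / (n_fft * d)` for integer `q`
#' (fftshifted so 0 is central). The stored image is cropped to the bed
#' region: a `[range_min, range_max)` window and `n_phi` (`n_theta`) central
#' azimuth (elevation) bins.
#'
#' Defaults reproduce a 128 x 64 x 64 FFT cropped to 72 x 17 x 25
#' (range x azimuth x elevation) cells; the crop bounds themselves are not
#' uniquely determined by those counts and are configurable.
#'
#' @param waveform An [sfcw_waveform()].
#' @param geometry An [array_geometry()].
#' @param n_fft_range,n_fft_u,n_fft_v Zero-padded FFT sizes.
#' @param range_crop Length-2 numeric, kept range window in metres.
#' @param n_phi,n_theta Number of central direction-cosine bins kept along
#'   azimuth and elevation.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(waveform, geometry, n_fft_range = 128, n_fft_u = 64,
                       n_fft_v = 64, range_crop = c(0.30, 1.50),
                       n_phi = 17, n_theta = 25) {
  stopifnot(inherits(waveform, "sfcw_waveform"),
            inherits(geometry, "array_geometry"))
  stopifnot(n_fft_range >= waveform$L, n_fft_u >= geometry$M,
            n_fft_v >= geometry$N)
  rmax <- C0 / (2 * waveform$delta_f)
  if (range_crop[2] > rmax)
    stop("range_crop exceeds the unambiguous range of ", signif(rmax, 4),
         " m (range alias)")
  dr <- rmax / n_fft_range
  r_all <- (seq_len(n_fft_range) - 1) * dr
  r_idx <- which(r_all >= range_crop[1] & r_all < range_crop[2])
  if (length(r_idx) == 0) stop("empty range crop")

  if (n_phi %% 2 == 0 || n_theta %% 2 == 0)
    stop("n_phi and n_theta must be odd (symmetric angular crop)")
  du <- waveform$lambda0 / (geometry$d_rx * n_fft_u)
  dv <- waveform$lambda0 / (geometry$d_tx * n_fft_v)
  u_all <- (seq_len(n_fft_u) - 1 - n_fft_u / 2) * du   # fftshifted order
  v_all <- (seq_len(n_fft_v) - 1 - n_fft_v / 2) * dv
  u_idx <- pick_central_bins(u_all, n_phi)
  v_idx <- pick_central_bins(v_all, n_theta)
  if (any(abs(u_all[u_idx]) >= 1) || any(abs(v_all[v_idx]) >= 1))
    stop("angular crop includes direction cosines with |u| or |v| >= 1; ",
         "reduce n_phi/n_theta")

  g <- list(waveform = waveform, geometry = geometry,
            n_fft_range = as.integer(n_fft_range),
            n_fft_u = as.integer(n_fft_u), n_fft_v = as.integer(n_fft_v),
            range_bin = dr, r_axis = r_all[r_idx], r_idx = r_idx,
            u_axis = u_all[u_idx], u_idx = u_idx,
            v_axis = v_all[v_idx], v_idx = v_idx,
            n_r = length(r_idx), n_phi = length(u_idx),
            n_theta = length(v_idx))
  class(g) <- "image_grid"
  g
}

pick_central_bins <- function(axis, n_keep) {
  if (n_keep > length(axis)) stop("crop larger than FFT extent")
  c0i <- which.min(abs(axis))  # bin closest to 0
  half <- (n_keep - 1) %/% 2
  idx <- (c0i - half):(c0i - half + n_keep - 1)
  if (idx[1] < 1 || idx[length(idx)] > length(axis))
    stop("crop window does not fit inside the FFT extent")
  idx
}

#' Angle axes of an image grid
#'
#' Labels the direction-cosine axes in angles: elevation `theta_l =
#' asin(v_l)` and azimuth `phi_k = asin(u_k)` (the exact azimuth of a cell is
#' `asin(u / cos(theta))`; the label axis is evaluated at `theta = 0`).
#'
#' @param grid An [image_grid()].
#' @return List with `phi` and `theta` label axes in radians and the matrix
#'   `phi_cell` of exact per-cell azimuth angles.
#' @export
angle_axes <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (any(abs(grid$u_axis) > 1) || any(abs(grid$v_axis) > 1))
    stop("direction cosines outside [-1, 1]")
  theta <- asin(grid$v_axis)
  phi <- asin(grid$u_axis)
  phi_cell <- outer(grid$u_axis, cos(theta), function(u, ct) {
    x <- u / ct
    x[abs(x) > 1] <- NA_real_
    asin(x)
  })
  list(phi = phi, theta = theta, phi_cell = phi_cell)
}

#' Radar configuration presets
#'
#' Bundles waveform, array geometry and image grid. The `"full"` preset is
#' the full-size bedside system (75 tones over 5.2 GHz, 20 x 20 elements,
#' 128/64/64 FFT, 72 x 17 x 25 crop, 20 Hz). The `"desk"` preset is a
#' reduced-size configuration used for simulation studies that keeps the
#' centre frequency, element spacing, tone step and frame rate, but uses 16
#' tones, 8 x 8 elements and a 48 x 24 x 24 FFT so that hundreds of seconds
#' of data can be simulated in seconds on one CPU core.
#'
#' @param preset `"full"` or `"desk"`.
#' @param ... Overrides passed to the component constructors:
#'   `n_steps`, `frame_interval`, `n_rx`, `n_tx`, `n_fft_range`, `n_fft_u`,
#'   `n_fft_v`, `range_crop`, `n_phi`, `n_theta`.
#' @return List with elements `waveform`, `geometry`, `grid` and the
#'   processing constants `tau` (window length, s) and `dtau` (overlap, s).
#' @export
radar_config <- function(preset = c("full", "desk"), ...) {
  preset <- match.arg(preset)
  ov <- list(...)
  def <- if (preset == "full") {
    list(n_steps = 75, bandwidth = 5.2e9, frame_interval = 0.05,
         n_rx = 20, n_tx = 20,
         n_fft_range = 128, n_fft_u = 64, n_fft_v = 64,
         range_crop = c(0.30, 1.50), n_phi = 17, n_theta = 25)
  } else {
    # 15 steps of the full-size tone spacing -> same unambiguous range
    list(n_steps = 16, bandwidth = 15 * (5.2e9 / 74), frame_interval = 0.05,
         n_rx = 8, n_tx = 8,
         n_fft_range = 48, n_fft_u = 24, n_fft_v = 24,
         range_crop = c(0.60, 1.80), n_phi = 15, n_theta = 15)
  }
  for (nm in names(ov)) def[[nm]] <- ov[[nm]]
  wf <- sfcw_waveform(f0 = 65.5e9, bandwidth = def$bandwidth,
                      n_steps = def$n_steps,
                      frame_interval = def$frame_interval)
  geo <- array_geometry(n_rx = def$n_rx, n_tx = def$n_tx)
  grid <- image_grid(wf, geo, n_fft_range = def$n_fft_range,
                     n_fft_u = def$n_fft_u, n_fft_v = def$n_fft_v,
                     range_crop = def$range_crop, n_phi = def$n_phi,
                     n_theta = def$n_theta)
  list(waveform = wf, geometry = geo, grid = grid, tau = 25, dtau = 5)
}
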