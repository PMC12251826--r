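#' Window function for sidelobe control
#'
#' @param n Length.
#' @param name `"hanning"` or `"rectangular"`.
#' @return Numeric vector of weights.
#' @export
taper_window <- function(n, name = c("hanning", "rectangular")) {
  name <- match.arg(name)
  if (n == 1) return(1)
  switch(name,
         hanning = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         rectangular = rep(1, n))
}

#' Reconstruct one complex 3D radar image (FFT fast path)
#'
#' Evaluates the spatially matched filter
#' \deqn{I(r,\phi,\vartheta) = \frac{1}{LMN} \sum_{n,m,\ell} w\, s\,
#'   e^{+j \frac{4\pi}{c_0} (\ell - L/2)\Delta f\, r}\,
#'   e^{+j k_0 [(m-1) d_{rx} u + (n-1) d_{tx} v]}}
#' on the grid's range / direction-cosine lattice by a zero-padded 3D FFT.
#' The phase is linear in `(r, u, v)`, so FFT bin centres are exact sample
#' points of the filter; no interpolation is involved. The crop stored in
#' `grid` is applied last.
#'
#' @param cube_frame Complex `L x M x N` array of one frame of raw samples.
#' @param grid An [image_grid()] (carries waveform and geometry).
#' @param window_name Separable taper applied along all three dimensions.
#' @return Complex `n_r x n_phi x n_theta` array with the grid attached as
#'   attribute `grid`.
#' @export
reconstruct_frame <- function(cube_frame, grid,
                              window_name = c("hanning", "rectangular")) {
  stopifnot(inherits(grid, "image_grid"))
  window_name <- match.arg(window_name)
  wf <- grid$waveform; geo <- grid$geometry
  d <- dim(cube_frame)
  if (is.null(d) || length(d) != 3 ||
      d[1] != wf$L || d[2] != geo$M || d[3] != geo$N)
    stop("cube_frame must be an L x M x N complex array matching the grid")

  wl <- taper_window(wf$L, window_name)
  wm <- taper_window(geo$M, window_name)
  wn <- taper_window(geo$N, window_name)
  x <- cube_frame * (wl %o% wm %o% wn)

  pad <- array(0 + 0i, c(grid$n_fft_range, grid$n_fft_u, grid$n_fft_v))
  pad[seq_len(wf$L), seq_len(geo$M), seq_len(geo$N)] <- x
  f <- fft(pad, inverse = TRUE)

  # tone index offset: phase uses (l - L/2) while the FFT index starts at 0
  p <- 0:(grid$n_fft_range - 1)
  shift <- exp(2i * pi * p * (1 - wf$L / 2) / grid$n_fft_range)
  f <- f * shift  # recycles down the first dimension

  # fftshift the two direction-cosine axes so 0 is central
  f <- f[, fftshift_idx(grid$n_fft_u), fftshift_idx(grid$n_fft_v), drop = FALSE]
  img <- f[grid$r_idx, grid$u_idx, grid$v_idx, drop = FALSE] /
    (wf$L * geo$M * geo$N)
  # The angular compensation is the conjugate of the exact propagation
  # phase, so the inverse-FFT bin +q holds direction cosine -q*du; with
  # the symmetric (odd-count) angular crop this is undone by reversing
  # the two angular dimensions, which labels each cell with the true
  # scatterer direction.
  img <- img[, grid$n_phi:1, grid$n_theta:1, drop = FALSE]
  attr(img, "grid") <- grid
  img
}

fftshift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

#' Direct matched-filter evaluation at arbitrary points
#'
#' Literal triple-sum form of the matched filter, usable at query points
#' that need not coincide with FFT bins. This is the slow reference the FFT
#' path is validated against.
#'
#' @param cube_frame Complex `L x M x N` array.
#' @param waveform An [sfcw_waveform()].
#' @param geometry An [array_geometry()].
#' @param query Data frame or list with components `r` (m), `phi`, `theta`
#'   (radians).
#' @param window_name Taper, as in [reconstruct_frame()].
#' @return Complex vector, one value per query point.
#' @export
matched_filter_direct <- function(cube_frame, waveform, geometry, query,
                                  window_name = c("hanning", "rectangular")) {
  window_name <- match.arg(window_name)
  L <- waveform$L; M <- geometry$M; N <- geometry$N
  w3 <- taper_window(L, window_name) %o% taper_window(M, window_name) %o%
    taper_window(N, window_name)
  x <- cube_frame * w3
  u <- cos(query$theta) * sin(query$phi)
  v <- sin(query$theta)
  lterm <- (seq_len(L) - L / 2) * waveform$delta_f * 4 * pi / C0
  mterm <- (seq_len(M) - 1) * geometry$d_rx * waveform$k0
  nterm <- (seq_len(N) - 1) * geometry$d_tx * waveform$k0
  # range term compensates the tone-dependent propagation phase; the
  # angular terms are the conjugate of the element-dependent phase of the
  # received signal, so the filter output peaks at the true direction
  vapply(seq_along(query$r), function(i) {
    ph <- (lterm * query$r[i]) %o% rep(1, M) %o% rep(1, N) -
      rep(1, L) %o% (mterm * u[i]) %o% rep(1, N) -
      rep(1, L) %o% rep(1, M) %o% (nterm * v[i])
    sum(x * exp(1i * ph)) / (L * M * N)
  }, complex(1))
}
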