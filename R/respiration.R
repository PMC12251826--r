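#' Partition the torso footprint into chest and abdomen masks
#'
#' The torso footprint is the angular bounding region of the four
#' shoulder/hip joints padded by one cell; it is split by the perpendicular
#' bisector of the xiphoid-navel segment in the azimuth-elevation plane,
#' with the chest on the shoulder side. Cells closer to the bisector than
#' `guard` are assigned to neither region: the imaging point-spread
#' function (about one beamwidth wide) mixes chest and abdomen motion in
#' the cells straddling the split line, and because those central torso
#' cells are also the brightest, including them would let the stronger
#' region dominate both amplitude-weighted traces.
#'
#' @param joints A [joint_set()] (estimated or ground truth).
#' @param grid An [image_grid()].
#' @param pad Number of padding cells around the bounding region.
#' @param guard Half-width of the excluded band around the bisector, in
#'   radians; defaults to half the Hanning-weighted azimuth beamwidth of
#'   the grid's array.
#' @return List of two logical `n_phi x n_theta` masks, `chest` and
#'   `abdomen` (disjoint).
#' @export
partition_torso <- function(joints, grid, pad = 1, guard = NULL) {
  if (is.null(guard)) {
    geo <- grid$geometry; wf <- grid$waveform
    guard <- 0.72 * wf$lambda0 / (geo$M * geo$d_rx)
  }
  partition_torso_impl(joints, grid, pad, guard)
}

partition_torso_impl <- function(joints, grid, pad, guard) {
  stopifnot(inherits(joints, "joint_set"), inherits(grid, "image_grid"))
  ax <- angle_axes(grid)
  j <- function(nm) unlist(joints[joints$joint == nm, c("phi", "theta")])
  xi <- j("xiphoid"); na <- j("navel")
  if (sqrt(sum((xi - na)^2)) < 1e-9)
    stop("degenerate joints: xiphoid and navel coincide")
  corners <- joints[joints$joint %in% c("left_shoulder", "right_shoulder",
                                        "left_hip", "right_hip"), ]
  dphi <- if (grid$n_phi > 1) diff(ax$phi[1:2]) else 0.1
  dth <- if (grid$n_theta > 1) diff(ax$theta[1:2]) else 0.1
  in_phi <- ax$phi >= min(corners$phi) - pad * abs(dphi) &
    ax$phi <= max(corners$phi) + pad * abs(dphi)
  in_th <- ax$theta >= min(corners$theta) - pad * abs(dth) &
    ax$theta <= max(corners$theta) + pad * abs(dth)
  fp <- outer(in_phi, in_th, `&`)

  mid <- (xi + na) / 2
  dirv <- xi - na  # points from navel toward xiphoid (shoulder side)
  sh <- colMeans(as.matrix(
    joints[joints$joint %in% c("left_shoulder", "right_shoulder"),
           c("phi", "theta")]))
  if (sum((sh - mid) * dirv) < 0) dirv <- -dirv
  dirv <- dirv / sqrt(sum(dirv^2))
  side <- outer(ax$phi - mid[1], rep(1, grid$n_theta)) * dirv[1] +
    outer(rep(1, grid$n_phi), ax$theta - mid[2]) * dirv[2]
  list(chest = fp & side >= guard, abdomen = fp & side <= -guard)
}

#' Region-averaged respiratory displacement
#'
#' For each cell in the mask the unwrapped phase is band-pass filtered
#' (0.05 to 6 Hz, zero-phase forward-backward 4th-order Butterworth, so the
#' breathing fundamental and its first harmonics are kept while the static
#' offset is removed), then the filtered signals are averaged with the mean
#' reflection amplitude of each cell as weight.
#'
#' Cells whose instantaneous amplitude fades below `min_amp_frac` of
#' their own mean are excluded before averaging: when a cell's return
#' passes through zero each breath, its unwrapped phase picks up
#' systematic near-2-pi slips at fixed breathing phases, which inject a
#' coherent harmonic comb into the averaged trace.
#'
#' @param merged Output of [merge_reduced()].
#' @param mask Logical `n_phi x n_theta` region mask.
#' @param band Pass band in Hz.
#' @param min_amp_frac Optional fade-rejection threshold as a fraction
#'   of the cell's mean amplitude (0 disables the gate; the gate is
#'   also skipped if it would empty the mask).
#' @return Numeric trace (radians of two-way phase; multiply by
#'   `lambda0 / (4 pi)` for metres), with attribute `times`.
#' @export
region_displacement <- function(merged, mask, band = c(0.05, 6),
                                min_amp_frac = 0) {
  if (!any(mask)) stop("empty region mask")
  fs <- merged$frame_rate
  stopifnot(band[2] < fs / 2)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  if (!is.null(merged$amin) && min_amp_frac > 0) {
    ok <- merged$amin >= min_amp_frac * merged$abar
    if (any(mask & ok)) mask <- mask & ok
  }
  cells <- which(mask, arr.ind = TRUE)
  num <- 0; den <- 0
  for (i in seq_len(nrow(cells))) {
    k <- cells[i, 1]; l <- cells[i, 2]
    zf <- signal::filtfilt(bf, merged$zeta[, k, l])
    w <- merged$abar[k, l]
    num <- num + w * zf
    den <- den + w
  }
  out <- num / den
  attr(out, "times") <- merged$times
  out
}

#' Breathing-rate estimation by STFT harmonic summation
#'
#' A short-time Fourier transform with `window` seconds per segment and
#' `hop` seconds advance is applied to the trace. For each segment the
#' fundamental is found by maximizing the weighted sum of the power at
#' the candidate frequency and its first `n_harmonics - 1` harmonics
#' over the respiration band, with weights `1/h`: the harmonic sum
#' prevents octave-down errors when the waveform has strong harmonics,
#' and the decaying weights prevent the converse octave-up error when
#' interference distortion puts broad harmonic combs into the spectrum.
#' Segments without a clear spectral peak (maximum score less than 3 dB
#' above the median score) are flagged low-quality and return no rate.
#'
#' @param trace Numeric respiratory trace.
#' @param fs Sampling rate in Hz.
#' @param band Candidate fundamental band in Hz.
#' @param n_harmonics Number of summed harmonics `H` (fundamental
#'   included).
#' @param window,hop STFT segment length and advance in seconds.
#' @param pad_factor Zero-padding factor of the segment FFT (refines the
#'   candidate grid).
#' @return Data frame with `time` (segment centre, s), `rate_cpm` (NA when
#'   flagged) and `quality` (`TRUE` for clear peaks).
#' @export
breathing_rate <- function(trace, fs, band = c(0.09, 0.70),
                           n_harmonics = 3, window = 40, hop = 5,
                           pad_factor = 8) {
  n <- length(trace)
  nw <- round(window * fs)
  if (n < nw) stop("trace shorter than one STFT window")
  nh <- round(hop * fs)
  starts <- seq(1, n - nw + 1, by = nh)
  nfft <- pad_factor * nw
  freqs <- (0:(nfft - 1)) * fs / nfft
  cand <- which(freqs >= band[1] & freqs <= band[2])
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  res <- lapply(starts, function(s0) {
    seg <- trace[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * taper  # the mean carries no rate information
    pw <- Mod(fft(c(seg, rep(0, nfft - nw))))^2
    score <- vapply(cand, function(ci) {
      sum(vapply(seq_len(n_harmonics), function(h) {
        hb <- round(h * (ci - 1)) + 1  # nearest bin of h * nu
        if (hb <= nfft / 2) pw[hb] / h else 0
      }, numeric(1)))
    }, numeric(1))
    # subharmonic preference: if a subharmonic of the top candidate
    # scores within 70% of it, the top candidate is an octave (or
    # higher) alias of the true fundamental. A clean fundamental is
    # immune (its subharmonic scores about half), but when
    # interference distortion puts a harmonic comb into the spectrum,
    # every multiple of the fundamental scores highly and the plain
    # argmax would land an octave up.
    best <- which.max(score)
    for (div in c(3L, 2L)) {
      sub <- round((cand[best] - 1) / div) + 1L
      si <- match(sub, cand)
      if (!is.na(si) && score[si] >= 0.7 * score[best]) best <- si
    }
    # quality: a clear peak 3 dB above the median score, carrying a
    # non-negligible share of the segment's total power
    ok <- max(score) >= 2 * median(score) &&
      max(score) > 1e-9 * sum(pw)
    data.frame(time = (s0 - 1 + nw / 2) / fs,
               rate_cpm = if (ok) freqs[cand[best]] * 60 else NA_real_,
               quality = ok)
  })
  do.call(rbind, res)
}

#' Phase-shift angle between two signal windows
#'
#' The angle `Theta = acos(<a, b> / (|a| |b|))` between two equal-length
#' signal vectors, in degrees within 0 to 180. For two same-frequency
#' sinusoids spanning several periods this approximates their phase
#' difference; values near 180 degrees indicate antiphase (paradoxical)
#' chest-abdomen motion.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Angle in degrees.
#' @export
phase_shift_angle <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm window")
  acos(min(max(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

#' Chest-abdomen phase-shift series
#'
#' Evaluates [phase_shift_angle()] on sliding windows of `window` seconds
#' centred on a regular time grid.
#'
#' @param ra,rc Abdomen and chest traces (equal length).
#' @param fs Sampling rate in Hz.
#' @param window Window length in seconds (default 15).
#' @param hop Evaluation grid step in seconds.
#' @param times Optional time axis of the traces (defaults to
#'   `0, 1/fs, ...`).
#' @return Data frame with `time` and `theta_deg`.
#' @export
phase_shift_series <- function(ra, rc, fs, window = 15, hop = 1,
                               times = NULL) {
  stopifnot(length(ra) == length(rc))
  n <- length(ra)
  if (is.null(times)) times <- (seq_len(n) - 1) / fs
  nw <- round(window * fs)
  if (n < nw) stop("traces shorter than the phase-shift window")
  nh <- max(1, round(hop * fs))
  starts <- seq(1, n - nw + 1, by = nh)
  theta <- vapply(starts, function(s0) {
    idx <- s0:(s0 + nw - 1)
    phase_shift_angle(ra[idx], rc[idx])
  }, numeric(1))
  data.frame(time = times[starts] + window / 2, theta_deg = theta)
}
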