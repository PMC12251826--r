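#' Split a recording into overlapping processing windows
#'
#' Windows have duration `tau` and overlap `dtau`, so consecutive starts
#' advance by `tau - dtau`; a trailing partial window is dropped.
#'
#' @param duration Recording duration in seconds.
#' @param tau Window length in seconds (default 25).
#' @param dtau Overlap in seconds (default 5).
#' @return Data frame with `t_start` and `t_end`; empty if
#'   `duration < tau`.
#' @export
split_windows <- function(duration, tau = 25, dtau = 5) {
  stopifnot(tau > dtau, dtau >= 0)
  if (duration < tau)
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  starts <- seq(0, duration - tau, by = tau - dtau)
  data.frame(t_start = starts, t_end = starts + tau)
}

#' Reduce an image-sequence window to its stored representation
#'
#' For each azimuth-elevation cell, the time-mean amplitude profile over
#' range is computed; `jMA` is the range index with the largest mean
#' amplitude (ties broken toward the smaller index), and the complex values
#' at that range, `I(t, r_jMA, phi_k, theta_l)`, are what is stored. `rMA`
#' is the per-frame range of maximum amplitude for each cell. Together
#' these reduce a 4D image sequence to two thin arrays while retaining the
#' phase evolution (breathing) and range evolution (gross movement) at
#' every cell.
#'
#' @param frames Complex `T x n_r x n_phi x n_theta` array (a window of
#'   reconstructed images).
#' @param grid The [image_grid()] the frames were reconstructed on.
#' @param frame_rate Frames per second.
#' @param t0 Window start time in seconds.
#' @return An object of class `reduced_window` with `values`
#'   (`T x n_phi x n_theta` complex), `jma` (index matrix), `rma`
#'   (`T x n_phi x n_theta`, metres), `amean` (`n_r x n_phi x n_theta`) and
#'   `abar` (`n_phi x n_theta`, the mean amplitude at `jMA`).
#' @export
reduce_window <- function(frames, grid, frame_rate, t0 = 0) {
  d <- dim(frames)
  stopifnot(length(d) == 4, d[1] >= 2)
  if (anyNA(frames)) stop("NaN in image frames")
  T <- d[1]; nr <- d[2]; np <- d[3]; nt <- d[4]
  stopifnot(nr == grid$n_r, np == grid$n_phi, nt == grid$n_theta)
  mag <- Mod(frames)

  amean <- array(colMeans(mag), c(nr, np, nt))
  jma <- apply(amean, c(2, 3), which.max)  # first max: ties to smaller index

  # gather values at r = jMA for every (t, phi, theta)
  cell <- expand.grid(t = seq_len(T), p = seq_len(np), l = seq_len(nt))
  jvec <- jma[cbind(cell$p, cell$l)]
  lin <- cell$t + T * (jvec - 1) + T * nr * (cell$p - 1) +
    T * nr * np * (cell$l - 1)
  values <- array(frames[lin], c(T, np, nt))

  # per-frame range of maximum amplitude
  m <- matrix(aperm(mag, c(1, 3, 4, 2)), ncol = nr)
  idx <- max.col(m, ties.method = "first")
  rma <- array(grid$r_axis[idx], c(T, np, nt))

  abar <- apply(array(Mod(values), c(T, np, nt)), c(2, 3), mean)
  rw <- list(values = values, jma = jma, rma = rma, amean = amean,
             abar = abar, t0 = t0, frame_rate = frame_rate,
             tau = T / frame_rate, grid = grid)
  class(rw) <- "reduced_window"
  rw
}

#' Reconstruct and reduce one processing window
#'
#' Streams frame-by-frame reconstruction into [reduce_window()] so the full
#' 4D image sequence for a window is held only once.
#'
#' @param cube A `raw_cube`.
#' @param grid An [image_grid()].
#' @param t_start,t_end Window bounds in seconds (frames with
#'   `t_start <= t < t_end`).
#' @param window_name Taper for [reconstruct_frame()].
#' @return A `reduced_window`.
#' @export
reduce_cube_window <- function(cube, grid, t_start, t_end,
                               window_name = "hanning") {
  sel <- which(cube$times >= t_start - 1e-9 & cube$times < t_end - 1e-9)
  if (length(sel) < 2) stop("window contains fewer than 2 frames")
  T <- length(sel)
  frames <- array(0 + 0i, c(T, grid$n_r, grid$n_phi, grid$n_theta))
  for (i in seq_len(T)) {
    fr <- cube$samples[sel[i], , , , drop = TRUE]
    dim(fr) <- dim(cube$samples)[2:4]
    frames[i, , , ] <- reconstruct_frame(fr, grid, window_name)
  }
  fr_rate <- 1 / cube$waveform$frame_interval
  reduce_window(frames, grid, fr_rate, t0 = cube$times[sel[1]])
}

#' Merge reduced windows along time
#'
#' Concatenates the unwrapped per-cell phase of consecutive overlapping
#' windows into one continuous series: within the overlap, samples come
#' from the later window after a constant phase offset (the mean difference
#' over the overlap) is matched, which removes jumps caused by a change of
#' the selected range bin between windows. Amplitudes `abar` are averaged
#' across windows.
#'
#' @param windows List of `reduced_window` objects in time order with
#'   constant overlap.
#' @return List with `zeta` (`T_total x n_phi x n_theta` unwrapped phase),
#'   `abar`, `amin` (per-cell minimum instantaneous amplitude, used to
#'   recognize cells that fade through zero), `times`, `frame_rate` and
#'   `grid`.
#' @export
merge_reduced <- function(windows) {
  stopifnot(length(windows) >= 1)
  w1 <- windows[[1]]
  np <- dim(w1$values)[2]; nt <- dim(w1$values)[3]
  fs <- w1$frame_rate
  zl <- lapply(windows, function(w) {
    z <- apply(Arg(w$values), c(2, 3), unwrap_phase)
    z  # T x np x nt
  })
  amin <- Reduce(pmin, lapply(windows, function(w)
    apply(Mod(w$values), c(2, 3), min)))
  zeta <- zl[[1]]
  if (length(windows) > 1) {
    for (i in 2:length(windows)) {
      prev_t0 <- windows[[i - 1]]$t0
      cur_t0 <- windows[[i]]$t0
      n_ov <- round((prev_t0 + windows[[i - 1]]$tau - cur_t0) * fs)
      stopifnot(n_ov >= 1)
      Tprev <- dim(zeta)[1]
      zi <- zl[[i]]
      off <- zeta[(Tprev - n_ov + 1):Tprev, , , drop = FALSE] -
        zi[1:n_ov, , , drop = FALSE]
      offm <- apply(off, c(2, 3), mean)
      Ti <- dim(zi)[1]
      adj <- zi[(n_ov + 1):Ti, , , drop = FALSE] +
        rep(offm, each = Ti - n_ov)
      zeta <- abind3(zeta, adj)
    }
  }
  abar <- Reduce(`+`, lapply(windows, `[[`, "abar")) / length(windows)
  times <- w1$t0 + (seq_len(dim(zeta)[1]) - 1) / fs
  list(zeta = zeta, abar = abar, amin = amin, times = times,
       frame_rate = fs, grid = w1$grid)
}

abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
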