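#' Detector thresholds
#'
#' Thresholds for the presence and movement classifiers. `delta_zeta_min`
#' (1.5 rad), `m_ts` (5 cells), the 0.5 s smoothing and the 5 s interval
#' follow the movement-detection recipe; `a_ts_mov_db` is the 30 dB
#' amplitude gate, interpreted relative to the window's own noise-floor
#' estimate (the median amplitude of the lowest-decile cells) because the
#' raw data carry no absolute radiometric calibration. The presence
#' thresholds `alpha1_ts` and `presence_count_min` are calibration values
#' chosen on synthetic scenes (the recipe, not the values, is prescribed).
#'
#' @param alpha1_ts Presence threshold on the `alpha1` indicator.
#' @param presence_count_min Minimum number of cells above `alpha1_ts`.
#' @param a_ts_mov_db Movement amplitude gate in dB below the window's
#'   peak mean amplitude.
#' @param delta_zeta_min Per-step phase-change threshold in radians.
#' @param m_ts Movement-indicator threshold in cells.
#' @param smoothing Moving-average length in seconds.
#' @param interval Classification interval in seconds.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(alpha1_ts = 0.02, presence_count_min = 10,
                            a_ts_mov_db = 30, delta_zeta_min = 1.5,
                            m_ts = 5, smoothing = 0.5, interval = 5) {
  stopifnot(alpha1_ts > 0, presence_count_min > 0, a_ts_mov_db > 0,
            delta_zeta_min > 0, m_ts > 0, smoothing > 0, interval > 0)
  cfg <- list(alpha1_ts = alpha1_ts,
              presence_count_min = presence_count_min,
              a_ts_mov_db = a_ts_mov_db, delta_zeta_min = delta_zeta_min,
              m_ts = m_ts, smoothing = smoothing, interval = interval)
  class(cfg) <- "detector_config"
  cfg
}

#' Presence detection from indicator maps
#'
#' A window is classified as "person present" when the number of
#' azimuth-elevation cells whose first phase-evolution indicator `alpha1`
#' exceeds `alpha1_ts` is larger than `presence_count_min`: breathing
#' produces in-band phase energy over the solid angle of the torso, which
#' an empty bed cannot.
#'
#' @param maps An `indicator_maps` object.
#' @param config A [detector_config()].
#' @return Logical.
#' @export
detect_presence <- function(maps, config = detector_config()) {
  stopifnot(inherits(maps, "indicator_maps"))
  sum(maps$az_el$alpha1 > config$alpha1_ts) > config$presence_count_min
}

#' Movement indicator series
#'
#' For every cell whose mean amplitude exceeds the gate (`a_ts_mov_db`
#' decibels below the window's peak mean amplitude - the raw data carry
#' no absolute radiometric calibration, and a peak-referenced gate is
#' invariant to global amplitude scaling of the window), the per-step
#' changes of the unwrapped phase are thresholded at `delta_zeta_min`;
#' the per-step count of cells above the threshold is smoothed with a
#' moving average over `smoothing` seconds. Breathing-induced phase
#' changes at the frame rate are far below the threshold, so the
#' indicator is dominated by fast limb or whole-body motion.
#'
#' @param reduced A `reduced_window`.
#' @param config A [detector_config()].
#' @return Data frame with `time` (s, the later sample of each step) and
#'   `count` (smoothed number of cells).
#' @export
movement_indicator <- function(reduced, config = detector_config()) {
  stopifnot(inherits(reduced, "reduced_window"))
  fs <- reduced$frame_rate
  gate <- max(reduced$abar) * 10^(-config$a_ts_mov_db / 20)
  cells <- which(reduced$abar >= gate, arr.ind = TRUE)
  T <- dim(reduced$values)[1]
  counts <- numeric(T - 1)
  for (i in seq_len(nrow(cells))) {
    z <- unwrap_phase(Arg(reduced$values[, cells[i, 1], cells[i, 2]]))
    counts <- counts + (abs(diff(z)) > config$delta_zeta_min)
  }
  # causal (trailing) moving average with zero-padded warm-up: counts
  # are attributed at or after the step that produced them, so movement
  # energy never leaks backwards across an interval boundary
  w <- max(1, round(config$smoothing * fs))
  sm <- as.numeric(stats::filter(c(rep(0, w - 1), counts),
                                 rep(1 / w, w), sides = 1))[w:(T - 2 + w)]
  data.frame(time = reduced$t0 + seq_len(T - 1) / fs, count = sm)
}

#' Classify fixed intervals as with/without movement
#'
#' An interval is labelled "with movement" iff the movement indicator
#' exceeds `m_ts` anywhere inside it. The interval grid is anchored at
#' `t_origin` (the recording start). Samples within the first
#' `smoothing` seconds of an interval are not used: the causal moving
#' average there still summarizes steps belonging to the previous
#' interval, and counting them would attribute a movement ending just
#' before a boundary to the following interval as well.
#'
#' @param indicator Data frame from [movement_indicator()] (several windows
#'   may be concatenated).
#' @param config A [detector_config()].
#' @param t_origin Interval grid origin in seconds.
#' @param t_end End of the covered span (defaults to the last indicator
#'   sample).
#' @return Data frame with `t_start`, `t_end`, `label`.
#' @export
classify_intervals <- function(indicator, config = detector_config(),
                               t_origin = 0, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(indicator$time)
  starts <- seq(t_origin, t_end - config$interval, by = config$interval)
  lab <- vapply(starts, function(s) {
    inw <- indicator$time > s + config$smoothing &
      indicator$time <= s + config$interval
    any(indicator$count[inw] > config$m_ts)
  }, logical(1))
  data.frame(t_start = starts, t_end = starts + config$interval,
             label = lab)
}
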