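#' Simulate a full recording and reduce it to windows
#'
#' End-to-end driver: scatterer trajectories, raw SFCW MIMO cube (with
#' optional noise), per-frame image reconstruction streamed into the
#' per-window reduction, and ground-truth labels.
#'
#' @param scene A `body_scene`.
#' @param script A [motion_script()].
#' @param duration Recording duration in seconds.
#' @param config A [radar_config()] bundle.
#' @param seed Seed for the noise realization.
#' @param snr_db Raw-data SNR (`Inf` for noiseless).
#' @param tau,dtau Window length and overlap in seconds.
#' @param exponent Specularity exponent for [view_weights()].
#' @param keep_cube Keep the raw cube in the result (memory permitting).
#' @return List with `windows` (list of `reduced_window`), `truth`,
#'   `times`, `config` and optionally `cube`.
#' @export
simulate_recording <- function(scene, script, duration, config,
                               seed = 1, snr_db = Inf, tau = 25, dtau = 5,
                               exponent = 4, keep_cube = FALSE) {
  dt <- config$waveform$frame_interval
  times <- seq(0, duration - dt / 2, by = dt)
  wins <- split_windows(duration, tau, dtau)
  if (nrow(wins) == 0) stop("recording shorter than one window")

  if (keep_cube) {
    traj <- scatterer_trajectories(scene, script, times)
    wt <- view_weights(scene, traj$pos, exponent = exponent)
    cube <- simulate_raw(traj, wt, config$geometry, config$waveform,
                         snr_db = snr_db, seed = seed)
    reduced <- lapply(seq_len(nrow(wins)), function(i)
      reduce_cube_window(cube, config$grid, wins$t_start[i], wins$t_end[i]))
  } else {
    # stream window by window so long recordings never hold the full raw
    # cube (overlap frames are re-simulated; the reduced representation
    # is what is kept)
    reduced <- lapply(seq_len(nrow(wins)), function(i) {
      tw <- times[times >= wins$t_start[i] - 1e-9 &
                    times < wins$t_end[i] - 1e-9]
      traj_w <- scatterer_trajectories(scene, script, tw)
      wt_w <- view_weights(scene, traj_w$pos, exponent = exponent)
      cube_w <- simulate_raw(traj_w, wt_w, config$geometry,
                             config$waveform, snr_db = snr_db,
                             seed = seed + i)
      reduce_cube_window(cube_w, config$grid, wins$t_start[i],
                         wins$t_end[i])
    })
  }
  truth <- ground_truth_labels(scene, script, c(0, duration))
  ref <- scatterer_trajectories(point_scene(rbind(c(0, 1, 0)),
                                            region = "clutter"),
                                script, times)
  out <- list(windows = reduced, truth = truth, times = times,
              window_spans = wins, config = config,
              trajectories = list(chest_disp = ref$chest_disp,
                                  abd_disp = ref$abd_disp))
  if (keep_cube) out$cube <- cube
  out
}
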