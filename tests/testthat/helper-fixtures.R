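# Shared fixtures. Simulation-backed objects are built lazily and cached
# for the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small waveform/geometry pair for oracle-level tests.
tiny_waveform <- function(L = 8) sfcw_waveform(n_steps = L,
                                               bandwidth = (L - 1) * 70.27e6)
tiny_geometry <- function(M = 4, N = 4) array_geometry(n_rx = M, n_tx = N)

# Desk-scale supine breathing recording (25 s), shared across tests.
desk_breathing <- function() fixture("desk_breathing", function() {
  cfg <- radar_config("desk")
  scene <- make_pose_scene("supine", 1.75, 0.40, seed = 11)
  script <- motion_script(breathing_rate = 12, amp_chest = 0.004,
                          amp_abd = 0.006, phase_offset = 10,
                          harmonic2_frac = 0.2)
  rec <- simulate_recording(scene, script, 25, cfg, seed = 11, snr_db = 20)
  list(cfg = cfg, scene = scene, script = script, rec = rec,
       maps = compute_indicators(rec$windows[[1]]))
})

# Hand-built reduced window: per-cell complex series with known phase,
# known rMA, on an arbitrary grid.
synthetic_reduced <- function(values, rma = NULL, grid = NULL,
                              frame_rate = 20) {
  d <- dim(values)
  if (is.null(grid)) {
    grid <- radar_config("desk")$grid
    stopifnot(d[2] <= grid$n_phi, d[3] <= grid$n_theta)
    grid$n_phi <- d[2]; grid$n_theta <- d[3]
    grid$u_axis <- grid$u_axis[seq_len(d[2])]
    grid$v_axis <- grid$v_axis[seq_len(d[3])]
  }
  if (is.null(rma)) rma <- array(grid$r_axis[1], d)
  amean <- array(1, c(grid$n_r, d[2], d[3]))
  abar <- apply(array(Mod(values), d), c(2, 3), mean)
  rw <- list(values = values, jma = matrix(1L, d[2], d[3]), rma = rma,
             amean = amean, abar = abar, t0 = 0, frame_rate = frame_rate,
             tau = d[1] / frame_rate, grid = grid)
  class(rw) <- "reduced_window"
  rw
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
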