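#' Simulation-study drivers
#'
#' These functions define the fixed synthetic study conditions used to
#' validate the pipeline end to end at desk scale: breathing-rate
#' recovery over the physiological rate span, chest-abdomen phase-shift
#' recovery with scripted antiphase episodes, limb-movement detection on a
#' scripted movement protocol, and the pose-network surrogate study on a
#' person-disjoint synthetic dataset. All are deterministic given the
#' seed.
#'
#' @name studies
NULL

# Deterministic per-person anthropometry (heights/widths spanning the
# volunteer ranges).
person_params <- function(i) {
  hs <- c(1.62, 1.75, 1.84, 1.58, 1.70, 1.88, 1.66, 1.79, 1.73, 1.61)
  ws <- c(0.36, 0.42, 0.46, 0.34, 0.40, 0.48, 0.38, 0.44, 0.41, 0.37)
  k <- ((i - 1) %% length(hs)) + 1
  list(height = hs[k], width = ws[k])
}

#' Breathing-rate recovery study
#'
#' One supine scene per scripted rate; the abdomen trace is extracted
#' with the ground-truth torso partition and the STFT harmonic-summation
#' estimator is compared with the scripted rate.
#'
#' @param rates Scripted rates in cycles/min.
#' @param snr_db Raw-data SNR (`Inf` = noiseless).
#' @param seed Integer seed.
#' @param duration Scene duration in seconds.
#' @param config Radar configuration (defaults to the desk preset).
#' @return List with per-scene data frame `per_scene` and scalar `mae`
#'   (cycles/min).
#' @export
study_rate_recovery <- function(rates = c(7, 10.5, 13, 16.5, 20, 24),
                                snr_db = Inf, seed = 1, duration = 120,
                                config = radar_config("desk")) {
  rows <- lapply(seq_along(rates), function(i) {
    pp <- person_params(i)
    scene <- make_pose_scene("supine", pp$height, pp$width,
                             seed = seed + 100 * i,
                             offset = c(0.05 * (i %% 3 - 1), 0.03 * (i %% 2)))
    script <- motion_script(breathing_rate = rates[i], amp_chest = 0.004,
                            amp_abd = 0.006, phase_offset = 10,
                            harmonic2_frac = 0.2)
    rec <- simulate_recording(scene, script, duration, config,
                              seed = seed + i, snr_db = snr_db)
    merged <- merge_reduced(rec$windows)
    # no guard band here: at this study's 8-element subarray the
    # chest-abdomen split is below the angular resolution, and for rate
    # estimation cross-region leakage is harmless (both regions share
    # the breathing fundamental)
    masks <- partition_torso(scene$joints, config$grid, guard = 0)
    tr <- region_displacement(merged, masks$abdomen)
    rs <- breathing_rate(tr, merged$frame_rate)
    est <- rs$rate_cpm[rs$quality]
    data.frame(rate_true = rates[i],
               rate_est = mean(est),
               mae = mean(abs(est - rates[i])),
               n_frames = sum(rs$quality))
  })
  per_scene <- do.call(rbind, rows)
  list(per_scene = per_scene, mae = mean(per_scene$mae))
}

#' Chest-abdomen phase-shift recovery study
#'
#' Supine scenes with a scripted antiphase episode. The radar estimate
#' of the windowed phase-shift angle is compared with the reference angle
#' obtained by applying the same estimator to the scripted chest and
#' abdomen displacement series (the synthetic counterpart of the
#' reference belts; the windowed angle itself is biased where the window
#' straddles an episode edge, so the comparison uses matched estimators).
#'
#' @param n_persons Number of synthetic persons.
#' @param seed Integer seed.
#' @param duration Scene duration in seconds.
#' @param episode `c(t_start, duration)` of the antiphase episode.
#' @param config Radar configuration; separating chest from abdomen
#'   motion requires the full angular aperture (20 x 20 elements), so the
#'   default keeps the full array and reduces only the tone count.
#' @return List with per-person data frame (`err_inside`: max estimator
#'   disagreement over windows centred inside the episode; `theta_out`:
#'   max radar angle over windows clear of the episode) and scalars
#'   `max_err_inside`, `max_theta_outside`.
#' @export
study_phase_shift <- function(n_persons = 8, seed = 1, duration = 85,
                              episode = c(40, 10),
                              config = radar_config("desk", n_rx = 20,
                                                    n_tx = 20,
                                                    n_fft_u = 48,
                                                    n_fft_v = 48,
                                                    n_phi = 15,
                                                    n_theta = 19,
                                                    frame_interval = 0.0625)) {
  rows <- lapply(seq_len(n_persons), function(i) {
    pp <- person_params(i)
    scene <- make_pose_scene("supine", pp$height, pp$width,
                             seed = seed + 200 * i,
                             offset = c(0.04 * (i %% 3 - 1), 0))
    script <- motion_script(breathing_rate = 10 + i, amp_chest = 0.0045,
                            amp_abd = 0.006, phase_offset = 10,
                            harmonic2_frac = 0.15,
                            asynchrony_events = data.frame(
                              t_start = episode[1], duration = episode[2]))
    rec <- simulate_recording(scene, script, duration, config,
                              seed = seed + i, snr_db = 20)
    merged <- merge_reduced(rec$windows)
    masks <- partition_torso(scene$joints, config$grid)
    ra <- region_displacement(merged, masks$abdomen)
    rc <- region_displacement(merged, masks$chest)
    est <- phase_shift_series(ra, rc, merged$frame_rate,
                              times = merged$times)
    fs <- merged$frame_rate
    n <- length(merged$times)
    ref <- phase_shift_series(rec$trajectories$abd_disp[seq_len(n)],
                              rec$trajectories$chest_disp[seq_len(n)],
                              fs, times = merged$times)
    stopifnot(nrow(est) == nrow(ref))
    t0 <- episode[1]; t1 <- episode[1] + episode[2]
    inside <- est$time >= t0 & est$time <= t1
    # clear-of-episode windows, excluding windows that touch the first
    # or last 5 s of the merged trace where the zero-phase band-pass
    # has edge transients
    tspan <- range(merged$times)
    clear <- (est$time < t0 - 8 | est$time > t1 + 8) &
      est$time > tspan[1] + 12.5 & est$time < tspan[2] - 12.5
    data.frame(person = i,
               err_inside = max(abs(est$theta_deg[inside] -
                                      ref$theta_deg[inside])),
               theta_in_peak = max(est$theta_deg[inside]),
               theta_out = max(est$theta_deg[clear]))
  })
  per <- do.call(rbind, rows)
  list(per_person = per, max_err_inside = max(per$err_inside),
       max_theta_outside = max(per$theta_out))
}

#' Scripted limb-movement protocol
#'
#' A movement script with `n_limb` single-limb movements (amplitude 5 to
#' 30 cm, duration 1 to 5 s, random limb) and `n_pose` whole-body shifts,
#' separated by rest gaps. Limb movements are modelled as lifting the
#' limb off the mattress and back (direction scattered around the
#' world-up axis), whole-body shifts as mostly horizontal rolls across
#' the bed - the kinematics of a person lying down.
#'
#' @param seed Integer seed.
#' @param n_limb,n_pose Event counts.
#' @param t_first First event start in seconds.
#' @param gap Range of rest gaps between events in seconds.
#' @param bed_geometry Radar mounting, used to express the directions in
#'   the radar frame.
#' @return A [motion_script()] and the protocol duration, as a list.
#' @export
movement_protocol <- function(seed = 1, n_limb = 41, n_pose = 4,
                              t_first = 8, gap = c(8, 16),
                              bed_geometry = list(dr = 0.8, hr = 0.9,
                                                  du = 0.9, alpha = 55)) {
  rng <- local_rng(seed)
  n <- n_limb + n_pose
  kind <- rep(c("limb", "body"), c(n_limb, n_pose))
  kind <- kind[order(rng$runif(n))]
  dur <- rng$runif(n, 1, 5)
  disp <- ifelse(kind == "limb", rng$runif(n, 0.05, 0.30),
                 rng$runif(n, 0.15, 0.35))
  base <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)   # lift: world up
  roll <- cbind(0, sign(rng$runif(n) - 0.5), 0)         # roll: across bed
  dirs_w <- ifelse(matrix(kind == "limb", n, 3), base, roll) +
    0.5 * matrix(rng$rnorm(3 * n), ncol = 3)
  tr <- bed_transform(bed_geometry)
  dirs <- world_to_radar_dir(dirs_w, tr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  t0 <- numeric(n)
  t <- t_first
  gaps <- rng$runif(n, gap[1], gap[2])
  for (i in seq_len(n)) {
    t0[i] <- t
    t <- t + dur[i] + gaps[i]
  }
  ev <- data.frame(t_start = t0, duration = dur, displacement = disp,
                   region = kind, limb = 1L + (seq_len(n) %% 4),
                   dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
  rng$done()
  # quiet natural breathing between the scripted movements
  script <- motion_script(breathing_rate = 13, amp_chest = 0.0025,
                          amp_abd = 0.0035, phase_offset = 10,
                          harmonic2_frac = 0.15, movement_events = ev)
  list(script = script, duration = t)
}

#' Limb-movement detection study
#'
#' Runs the movement protocol through the full pipeline and classifies
#' 5 s intervals with the threshold detector; returns the confusion
#' matrix against the ground-truth overlap labels.
#'
#' @param seed Integer seed.
#' @param config Radar configuration; the default keeps the full 20 x 20
#'   array and 32 tones: separating resting limbs from the breathing
#'   torso needs both the angular aperture and enough range resolution,
#'   and the azimuth crop must be wide enough to cover leg positions.
#' @param detector A [detector_config()].
#' @return List with `confusion`, `accuracy` and the label/indicator
#'   frames.
#' @export
study_movement <- function(seed = 1,
                           config = radar_config("desk", n_steps = 32,
                                                 bandwidth = 31 * (5.2e9 / 74),
                                                 n_rx = 20, n_tx = 20,
                                                 n_fft_range = 48,
                                                 n_fft_u = 48, n_fft_v = 32,
                                                 n_phi = 33, n_theta = 15),
                           detector = detector_config()) {
  prot <- movement_protocol(seed)
  pp <- person_params(2)
  scene <- make_pose_scene("supine", pp$height, pp$width, seed = seed + 7)
  rec <- simulate_recording(scene, prot$script, prot$duration, config,
                            seed = seed, snr_db = 15)
  ind <- do.call(rbind, lapply(rec$windows, movement_indicator,
                               config = detector))
  dur_cov <- max(vapply(rec$windows, function(w) w$t0 + w$tau, numeric(1)))
  dur_cov <- 5 * floor(dur_cov / 5)
  pred <- classify_intervals(ind, detector, t_origin = 0, t_end = dur_cov)
  truth <- ground_truth_labels(scene, prot$script, c(0, dur_cov),
                               interval = detector$interval)
  stopifnot(nrow(pred) == nrow(truth$movement_labels))
  cm <- confusion_matrix(truth$movement_labels$label, pred$label,
                         levels = c(TRUE, FALSE))
  list(confusion = cm, accuracy = categorical_accuracy(cm),
       pred = pred, truth = truth$movement_labels, indicator = ind)
}

#' Synthetic pose/joint dataset
#'
#' Windows of indicator heatmaps with ground-truth pose class and joints,
#' for several synthetic persons in the three pose classes with varying
#' placement on the bed - the surrogate for a pose-measurement campaign.
#' One reduced window is simulated per (person, pose, repetition) with a
#' fresh placement and breathing script.
#'
#' @param n_persons Number of synthetic persons (>= 3).
#' @param windows_per_pose Repetitions per person and pose class.
#' @param seed Integer seed.
#' @param snr_db Raw-data SNR.
#' @param config Radar configuration; the default keeps the full 20 x 20
#'   aperture (joint localization needs the angular resolution) with 16
#'   tones, an 8 Hz frame rate and 16 s windows.
#' @return List with `x1`, `x2` (flattened heatmap matrices, one column
#'   per window), `shapes`, `pose` (integer 1 = supine, 2 = prone,
#'   3 = lateral), `joints` (list of [joint_set()]), and `manifest`.
#' @export
generate_pose_dataset <- function(n_persons = 8, windows_per_pose = 13,
                                  seed = 1, snr_db = 20,
                                  config = radar_config(
                                    "desk", n_rx = 20, n_tx = 20,
                                    n_fft_u = 32, n_fft_v = 32,
                                    n_phi = 17, n_theta = 21,
                                    frame_interval = 0.125)) {
  poses <- c("supine", "prone", "lateral")
  tau <- 16
  manifest <- expand.grid(rep = seq_len(windows_per_pose),
                          pose = seq_along(poses),
                          person = seq_len(n_persons))
  n <- nrow(manifest)
  x1 <- x2 <- NULL
  joints <- vector("list", n)
  rng <- local_rng(seed)
  offs <- cbind(rng$runif(n, -0.20, 0.20), rng$runif(n, -0.15, 0.15))
  rates <- rng$runif(n, 9, 22)
  ampc <- rng$runif(n, 0.003, 0.006)
  ampa <- rng$runif(n, 0.004, 0.008)
  scene_seeds <- floor(rng$runif(n, 1, 1e8))
  rng$done()
  for (i in seq_len(n)) {
    pp <- person_params(manifest$person[i])
    scene <- make_pose_scene(poses[manifest$pose[i]], pp$height, pp$width,
                             seed = scene_seeds[i], offset = offs[i, ],
                             n_torso = 200)
    script <- motion_script(breathing_rate = rates[i], amp_chest = ampc[i],
                            amp_abd = ampa[i], phase_offset = 10,
                            harmonic2_frac = 0.15)
    rec <- simulate_recording(scene, script, tau, config,
                              seed = scene_seeds[i] + 1, snr_db = snr_db,
                              tau = tau, dtau = 0)
    hm <- to_heatmaps(compute_indicators(rec$windows[[1]]))
    if (is.null(x1)) {
      shapes <- list(dim(hm$az_el), dim(hm$el_dist))
      x1 <- matrix(0, prod(shapes[[1]]), n)
      x2 <- matrix(0, prod(shapes[[2]]), n)
    }
    x1[, i] <- as.vector(hm$az_el)
    x2[, i] <- as.vector(hm$el_dist)
    joints[[i]] <- scene$joints
  }
  list(x1 = x1, x2 = x2, shapes = shapes, pose = manifest$pose,
       joints = joints, manifest = manifest, config = config)
}

#' Pose-network surrogate study
#'
#' Trains the forked CNN on a person-disjoint split of a synthetic
#' dataset: pose classification (categorical accuracy on held-out
#' persons) and joint regression (xiphoid x-z MAE compared with the
#' mean-of-training-set baseline predictor).
#'
#' @param dataset Output of [generate_pose_dataset()].
#' @param seed Integer seed.
#' @param test_persons,val_persons Person ids for the held-out and
#'   validation splits.
#' @param epochs_cls,epochs_reg Maximum training epochs for the
#'   classification and regression heads (regression needs far more to
#'   converge past the predict-the-mean plateau).
#' @return List with `pose_accuracy`, `confusion`, `xz_mae_test`
#'   (per-joint cm), `xz_mae_baseline`, `angular_test_deg` and the
#'   trained models.
#' @export
study_pose_net <- function(dataset, seed = 1,
                           test_persons = c(7, 8), val_persons = 6,
                           epochs_cls = 100, epochs_reg = 250) {
  person <- dataset$manifest$person
  sp <- make_person_split(person, test_persons, val_persons)
  shapes <- dataset$shapes

  cfgc <- forked_net_config(shapes, head = "classification",
                            dropout = c(0.15, 0.3))
  netc <- build_forked_net(cfgc, seed = seed)
  trc <- train_forked_net(netc, dataset$x1, dataset$x2, dataset$pose,
                          sp$train, sp$val, epochs = epochs_cls,
                          lr = 3e-3, patience = 20, seed = seed)
  pr <- net_forward(trc$net, list(x1 = dataset$x1[, sp$test, drop = FALSE],
                                  x2 = dataset$x2[, sp$test, drop = FALSE]))
  pred_cls <- apply(pr$out, 2, which.max)
  cm <- confusion_matrix(dataset$pose[sp$test], pred_cls, levels = 1:3)
  acc <- categorical_accuracy(cm)

  enc <- encode_joint_targets(dataset$joints[sp$train])
  y <- list(u = sapply(dataset$joints, function(j) j$x / j$r),
            v = sapply(dataset$joints, function(j) j$z / j$r),
            rn = (sapply(dataset$joints, function(j) j$r) - enc$r_mean) /
              enc$r_sd)
  cfgr <- forked_net_config(shapes, head = "regression",
                            dropout = c(0.1, 0.2))
  netr <- build_forked_net(cfgr, seed = seed + 1)
  trr <- train_forked_net(netr, dataset$x1, dataset$x2, y,
                          sp$train, sp$val, epochs = epochs_reg,
                          lr = 3e-3, patience = 50, seed = seed + 1)
  pj <- net_forward(trr$net, list(x1 = dataset$x1[, sp$test, drop = FALSE],
                                  x2 = dataset$x2[, sp$test, drop = FALSE]))
  pred_joints <- decode_joint_outputs(pj$out, enc$r_mean, enc$r_sd)
  true_test <- dataset$joints[sp$test]
  mae <- xz_mae(true_test, pred_joints)

  # mean-of-training-set baseline predictor
  base_enc <- rbind(y$u, y$v, y$rn)  # 18 x n grouped by coordinate
  ord <- as.vector(t(matrix(1:18, 6, 3)))  # regroup to (u,v,rn) per joint
  base_vec <- rowMeans(base_enc[, sp$train, drop = FALSE])[ord]
  base_out <- matrix(base_vec, 18, length(sp$test))
  base_joints <- decode_joint_outputs(base_out, enc$r_mean, enc$r_sd)
  mae_base <- xz_mae(true_test, base_joints)

  ang <- angular_loss(true_test, pred_joints)
  list(pose_accuracy = acc, confusion = cm, xz_mae_test = mae,
       xz_mae_baseline = mae_base, angular_test_deg = ang,
       classifier = trc, regressor = trr, split = sp,
       norm = list(r_mean = enc$r_mean, r_sd = enc$r_sd))
}
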