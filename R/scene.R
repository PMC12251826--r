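#' Synthetic body scenes for a bedside radar
#'
#' A scene is a set of point scatterers (torso surface, head, limbs, static
#' clutter) with reflectivities, outward surface normals and region labels,
#' plus the ground-truth torso joints. The body is constructed
#' anatomically in a bed-fixed world frame (x along the bed, z up) and then
#' rigidly transformed into the radar frame: the radar sits beside the bed
#' at horizontal distance `dr` and height `hr` above the mattress, boresight
#' aimed at the bed centre, with the TX axis kept in the vertical plane.
#'
#' The torso is the upper half of an elliptic cylinder sampled with at
#' least 200 surface scatterers. Pose classes differ by the roll of the
#' body about its long axis: supine exposes the chest/abdomen front (full
#' breathing amplitude), prone exposes the back (attenuated breathing),
#' lateral exposes the body side (intermediate amplitude, narrower vertical
#' footprint). Joints are placed at fixed anthropometric fractions of the
#' person's height: xiphoid at 72% and navel at 60% of height from the
#' feet, shoulders at 82% and hips at 48% with a lateral offset of half
#' the person's width.
#'
#' @param pose_class One of `"supine"`, `"prone"`, `"lateral"`.
#' @param person_height Height in metres (1.50 to 1.90).
#' @param person_width Shoulder width in metres (0.25 to 0.55).
#' @param seed Integer seed; the scene is deterministic given the seed.
#' @param offset Length-2 numeric, placement offset of the torso centre on
#'   the bed (along, across) in metres.
#' @param n_torso Number of torso surface scatterers (>= 200).
#' @param bed_geometry Named list `dr`, `hr`, `du` (m) and `alpha` (deg)
#'   describing the radar mounting next to the bed.
#' @return An object of class `body_scene`.
#' @export
make_pose_scene <- function(pose_class, person_height = 1.75,
                            person_width = 0.40, seed = 1,
                            offset = c(0, 0), n_torso = 220,
                            bed_geometry = list(dr = 0.8, hr = 0.9,
                                                du = 0.9, alpha = 55)) {
  if (!pose_class %in% c("supine", "prone", "lateral"))
    stop("unknown pose_class '", pose_class,
         "'; expected supine, prone or lateral")
  stopifnot(person_height >= 1.50, person_height <= 1.90,
            person_width >= 0.25, person_width <= 0.55,
            n_torso >= 200)
  h <- person_height; a <- person_width / 2; b <- 0.11
  ox <- offset[1]; oy <- offset[2]

  rng <- local_rng(seed)
  # torso surface: longitudinal fraction s (of height, measured from feet)
  # and circumferential angle psi measured from the bed-up direction.
  # Pose classes differ structurally: prone exposes the flatter back
  # (larger half-depth, narrower angular fan) with breathing motion
  # concentrated toward the lower back; lateral rolls the body 90 degrees
  # so the width is vertical and the anterior surface faces the radar.
  s <- rng$runif(n_torso, 0.48, 0.82)
  if (pose_class == "prone") b <- 0.13
  psi_max <- switch(pose_class, supine = 1.55, prone = 1.15,
                    lateral = 1.45)
  psi <- rng$runif(n_torso, -psi_max, psi_max)
  xw <- ox + (s - 0.65) * h
  if (pose_class == "lateral") {
    # rolled 90 deg about the body axis: width vertical, depth across bed
    zc <- a
    yw <- oy + b * sin(psi); zw <- zc + a * cos(psi)
    nw <- cbind(0, sin(psi) / b, cos(psi) / a)
  } else {
    zc <- b
    yw <- oy + a * sin(psi); zw <- zc + b * cos(psi)
    nw <- cbind(0, sin(psi) / a, cos(psi) / b)
  }
  nw <- nw / sqrt(rowSums(nw^2))
  torso_pos <- cbind(xw, yw, zw)
  region <- ifelse(s > 0.66, "chest", "abdomen")
  sfrac <- (s - 0.48) / (0.82 - 0.48)  # 0 at hips, 1 at shoulders
  breath_scale <- switch(pose_class,
                         supine = rep(1.0, n_torso),
                         prone = 0.5 - 0.3 * sfrac,
                         lateral = rep(0.6, n_torso))
  refl_torso <- exp(rng$rnorm(n_torso, 0, 0.25))

  # head: static sphere cap near 93% height
  n_head <- 24
  hps <- rng$rnorm(n_head * 3)
  hps <- matrix(hps, ncol = 3); hps <- hps / sqrt(rowSums(hps^2)) * 0.09
  hps[, 3] <- abs(hps[, 3])
  head_pos <- cbind(ox + (0.93 - 0.65) * h + hps[, 1], oy + hps[, 2],
                    0.10 + hps[, 3])
  head_nrm <- hps / 0.09

  # limbs: two arms beside (or in front of) the torso, two legs below
  half_y <- if (pose_class == "lateral") b else a
  half_z <- if (pose_class == "lateral") 2 * a else 2 * b
  limb <- list()
  n_arm <- 56; n_leg <- 36  # surface patches, not lines: an arm or leg
  for (side in c(-1, 1)) {  # spans several resolution cells in width too
    sa <- rng$runif(n_arm, 0.45, 0.78)
    limb[[length(limb) + 1]] <- list(
      pos = cbind(ox + (sa - 0.65) * h,
                  oy + side * (half_y + 0.06) + rng$runif(n_arm, -0.04, 0.04),
                  pmin(half_z * 0.7, 0.14) + rng$runif(n_arm, -0.03, 0.03)),
      id = if (side < 0) 1L else 2L, s = sa)
  }
  for (side in c(-1, 1)) {
    sl <- rng$runif(n_leg, 0.08, 0.46)
    limb[[length(limb) + 1]] <- list(
      pos = cbind(ox + (sl - 0.65) * h,
                  oy + side * 0.10 + rng$runif(n_leg, -0.05, 0.05),
                  0.08 + rng$runif(n_leg, -0.03, 0.03)),
      id = if (side < 0) 3L else 4L, s = sl)
  }
  limb_pos <- do.call(rbind, lapply(limb, `[[`, "pos"))
  limb_id <- unlist(lapply(limb, function(l) rep(l$id, nrow(l$pos))))
  limb_s <- unlist(lapply(limb, `[[`, "s"))
  # limbs are roughly cylindrical: their specular line always faces the
  # radar, so the effective normal points from the limb toward the radar
  limb_radar <- world_to_radar(limb_pos, bed_transform(bed_geometry))
  limb_nrm_r <- -limb_radar / sqrt(rowSums(limb_radar^2))
  tr0 <- bed_transform(bed_geometry)
  limb_nrm <- t(solve(tr0$R) %*% t(limb_nrm_r))  # back to world frame

  # static clutter: bed frame, wall, furniture - at the bed periphery,
  # outside the body volume (the mattress under the person is shadowed)
  n_cl <- 12
  cl_side <- sign(rng$runif(n_cl) - 0.5)
  cl_pos <- cbind(rng$runif(n_cl, ox - 1.0, ox + 1.0),
                  cl_side * rng$runif(n_cl, half_y + 0.25, 0.7),
                  rng$runif(n_cl, 0.0, 0.25))
  cl_nrm <- cbind(0, rep(-0.7, n_cl), 0.71)

  pos_w <- rbind(torso_pos, head_pos, limb_pos, cl_pos)
  nrm_w <- rbind(nw, head_nrm, limb_nrm, cl_nrm)
  nrm_w <- nrm_w / sqrt(rowSums(nrm_w^2))
  regions <- c(region, rep("head", n_head), rep("limb", nrow(limb_pos)),
               rep("clutter", n_cl))
  refl <- c(refl_torso, rep(0.8, n_head), rep(1.0, nrow(limb_pos)),
            rep(0.25, n_cl))
  bscale <- c(breath_scale, rep(0, n_head),
              ifelse(limb_id <= 2L, 0.3, 0.1),  # arms follow more than legs
              rep(0, n_cl))
  lid <- c(rep(0L, n_torso), rep(0L, n_head), limb_id, rep(0L, n_cl))

  # joints in the world frame
  front_at <- function(sj) {
    x <- ox + (sj - 0.65) * h
    switch(pose_class,
           supine = c(x, oy, zc + b),
           prone = c(x, oy, max(zc - b, 0.02)),
           lateral = c(x, oy - b, zc))  # front faces the radar side
  }
  lat_at <- function(sj, side) {
    x <- ox + (sj - 0.65) * h
    if (pose_class == "lateral") c(x, oy, zc + side * a)
    else c(x, oy + side * a, zc)
  }
  jw <- rbind(xiphoid = front_at(0.72), navel = front_at(0.60),
              left_shoulder = lat_at(0.82, 1), right_shoulder = lat_at(0.82, -1),
              left_hip = lat_at(0.48, 1), right_hip = lat_at(0.48, -1))

  # hidden half of the torso circumference: near-zero aspect weight for
  # the radar, but part of the body for geometric consistency (drawn
  # after all other random quantities so their realizations are
  # unaffected by its presence)
  n_hid <- 40
  s_h <- rng$runif(n_hid, 0.48, 0.82)
  psi_h <- sign(rng$runif(n_hid, -1, 1)) * rng$runif(n_hid, psi_max, pi)
  x_h <- ox + (s_h - 0.65) * h
  if (pose_class == "lateral") {
    hpos <- cbind(x_h, oy + b * sin(psi_h), a + a * cos(psi_h))
    hnrm <- cbind(0, sin(psi_h) / b, cos(psi_h) / a)
  } else {
    hpos <- cbind(x_h, oy + a * sin(psi_h), zc + b * cos(psi_h))
    hnrm <- cbind(0, sin(psi_h) / a, cos(psi_h) / b)
  }
  hpos[, 3] <- pmax(hpos[, 3], 0)  # resting on the mattress
  hnrm <- hnrm / sqrt(rowSums(hnrm^2))
  pos_w <- rbind(pos_w, hpos)
  nrm_w <- rbind(nrm_w, hnrm)
  regions <- c(regions, ifelse(s_h > 0.66, "chest", "abdomen"))
  refl <- c(refl, rep(1, n_hid))
  hscale <- switch(pose_class, supine = rep(1.0, n_hid),
                   prone = 0.5 - 0.3 * (s_h - 0.48) / 0.34,
                   lateral = rep(0.6, n_hid))
  bscale <- c(bscale, hscale)
  lid <- c(lid, rep(0L, n_hid))

  # anterior direction of the body (unit, world frame)
  anterior_w <- switch(pose_class, supine = c(0, 0, 1),
                       prone = c(0, 0, -1), lateral = c(0, -1, 0))

  # Breathing displacement direction: the torso wall moves as a coherent
  # unit, predominantly along the body's anterior axis, with a smaller
  # local-normal component (rib-cage expansion). Fully normal-directed
  # motion would make scatterers inside one resolution cell move
  # differentially by several radians of two-way phase per breath,
  # producing speckle fades and phase slips that a smooth, coherently
  # moving body surface does not exhibit.
  bdir_w <- 0.9 * matrix(anterior_w, n_torso, 3, byrow = TRUE) + 0.1 * nw
  bdir_w <- bdir_w / sqrt(rowSums(bdir_w^2))
  # limbs rest on or against the breathing trunk and move with the
  # trunk section they touch (attenuated, along the anterior axis); a
  # rigidly static bright limb beside the chest would inject an
  # arbitrary-phase component into the region-averaged respiratory
  # trace that real bodies do not produce
  bdir_limb <- matrix(anterior_w, nrow(limb_pos), 3, byrow = TRUE)
  bdir_hid <- 0.9 * matrix(anterior_w, n_hid, 3, byrow = TRUE) + 0.1 * hnrm
  bdir_hid <- bdir_hid / sqrt(rowSums(bdir_hid^2))
  bdir_all_w <- rbind(bdir_w, matrix(0, n_head, 3), bdir_limb,
                      matrix(0, n_cl, 3), bdir_hid)
  follows <- c(region, rep("none", n_head),
               ifelse(limb_s > 0.66, "chest", "abdomen"),
               rep("none", n_cl), ifelse(s_h > 0.66, "chest", "abdomen"))

  tr <- bed_transform(bed_geometry)
  scene <- list(
    anterior_world = anterior_w,
    anterior = as.vector(world_to_radar_dir(rbind(anterior_w), tr)),
    positions = world_to_radar(pos_w, tr),
    normals = world_to_radar_dir(nrm_w, tr),
    breath_dir = world_to_radar_dir(bdir_all_w, tr),
    reflectivity = refl, region = regions, breath_scale = bscale,
    follows = follows,
    limb_id = lid, pose_class = pose_class,
    joints = joint_set_from_xyz(world_to_radar(jw, tr)),
    person = list(height = person_height, width = person_width,
                  offset = offset, seed = seed),
    bed_geometry = bed_geometry, transform = tr,
    world_positions = pos_w, world_normals = nrm_w, presence = TRUE)
  class(scene) <- "body_scene"
  rng$done()
  scene
}

#' Minimal scene of explicit point scatterers
#'
#' A bare-bones scene for controlled experiments and closed-form checks:
#' scatterers are given directly in the radar frame.
#'
#' @param positions `S x 3` matrix of radar-frame positions in metres.
#' @param normals `S x 3` matrix of outward surface normals.
#' @param reflectivity Length-S nonnegative reflectivities.
#' @param region Length-S region labels (`chest`, `abdomen`, `head`,
#'   `limb`, `clutter`).
#' @param breath_scale Length-S breathing-amplitude scale (0 = static).
#' @return A `body_scene`.
#' @export
point_scene <- function(positions, normals = NULL,
                        reflectivity = rep(1, nrow(positions)),
                        region = rep("chest", nrow(positions)),
                        breath_scale = as.numeric(region %in%
                                                    c("chest", "abdomen"))) {
  positions <- rbind(positions)
  S <- nrow(positions)
  if (is.null(normals)) {
    normals <- -positions / sqrt(rowSums(positions^2))  # facing the radar
  }
  scene <- list(positions = positions, normals = rbind(normals),
                reflectivity = reflectivity, region = region,
                breath_scale = breath_scale, limb_id = rep(0L, S),
                pose_class = NA_character_, joints = NULL,
                bed_geometry = NULL, transform = NULL,
                presence = any(region %in% c("chest", "abdomen")))
  class(scene) <- "body_scene"
  scene
}

#' Empty-bed scene (clutter only)
#'
#' @param seed Integer seed.
#' @param n_clutter Number of static clutter points.
#' @inheritParams make_pose_scene
#' @return A `body_scene` with `presence = FALSE` and no person.
#' @export
make_empty_scene <- function(seed = 1, n_clutter = 20,
                             bed_geometry = list(dr = 0.8, hr = 0.9,
                                                 du = 0.9, alpha = 55)) {
  rng <- local_rng(seed)
  pos_w <- cbind(rng$runif(n_clutter, -0.9, 0.9),
                 rng$runif(n_clutter, -0.5, 0.5),
                 rng$runif(n_clutter, 0.0, 0.4))
  nrm_w <- cbind(0, rep(-0.7, n_clutter), 0.71)
  tr <- bed_transform(bed_geometry)
  scene <- list(positions = world_to_radar(pos_w, tr),
                normals = world_to_radar_dir(nrm_w, tr),
                reflectivity = rep(0.3, n_clutter),
                region = rep("clutter", n_clutter),
                breath_scale = rep(0, n_clutter),
                limb_id = rep(0L, n_clutter), pose_class = NA_character_,
                joints = NULL, bed_geometry = bed_geometry, transform = tr,
                world_positions = pos_w, world_normals = nrm_w,
                presence = FALSE)
  class(scene) <- "body_scene"
  rng$done()
  scene
}

# Rigid world (bed) -> radar transform: radar at (0, -dr, hr) in the world
# frame, boresight y-axis aimed at the bed centre, TX axis (z) in the
# vertical plane.
bed_transform <- function(bg) {
  radar_w <- c(0, -bg$dr, bg$hr)
  target <- c(0, 0, 0.15)
  yhat <- target - radar_w; yhat <- yhat / sqrt(sum(yhat^2))
  up <- c(0, 0, 1)
  zhat <- up - sum(up * yhat) * yhat; zhat <- zhat / sqrt(sum(zhat^2))
  xhat <- c(yhat[2] * zhat[3] - yhat[3] * zhat[2],
            yhat[3] * zhat[1] - yhat[1] * zhat[3],
            yhat[1] * zhat[2] - yhat[2] * zhat[1])
  list(origin = radar_w, R = rbind(xhat, yhat, zhat))
}

world_to_radar <- function(p, tr) {
  out <- t(tr$R %*% (t(p) - tr$origin))
  dimnames(out) <- list(rownames(p), c("x", "y", "z"))
  out
}

world_to_radar_dir <- function(d, tr) t(tr$R %*% t(d))

# Scoped RNG so scene construction is deterministic without touching the
# caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(runif = function(n, lo = 0, hi = 1) runif(n, lo, hi),
       rnorm = function(n, m = 0, s = 1) rnorm(n, m, s),
       done = function() {
         if (is.null(old)) rm(".Random.seed", envir = globalenv())
         else assign(".Random.seed", old, envir = globalenv())
       })
}

#' Breathing and movement script
#'
#' Describes the scripted kinematics of a scene: a sinusoidal breathing
#' waveform (with optional second harmonic) of given rate and per-region
#' amplitude, a chest-vs-abdomen phase offset, limb/body movement events
#' and asynchronous (antiphase) breathing episodes.
#'
#' @param breathing_rate Cycles per minute; either a scalar or a data frame
#'   `(time, rate)` defining a piecewise-constant rate (steps at `time`).
#' @param amp_chest,amp_abd Peak breathing displacement in metres (typical
#'   1 to 10 mm).
#' @param phase_offset Chest-vs-abdomen phase offset in degrees.
#' @param harmonic2_frac Relative amplitude of the second harmonic, in
#'   `[0, 1)`.
#' @param movement_events `NULL` or data frame with columns `t_start`,
#'   `duration` (s), `displacement` (m), `region` (`"limb"` or `"body"`),
#'   `limb` (1..4, ignored unless region is `"limb"`) and direction cosines
#'   `dx`, `dy`, `dz` (radar frame).
#' @param asynchrony_events `NULL` or data frame with columns `t_start`,
#'   `duration` during which chest and abdomen move in antiphase.
#' @return An object of class `motion_script`.
#' @export
motion_script <- function(breathing_rate = 14, amp_chest = 0.004,
                          amp_abd = 0.006, phase_offset = 10,
                          harmonic2_frac = 0.15, movement_events = NULL,
                          asynchrony_events = NULL) {
  rates <- if (is.data.frame(breathing_rate)) breathing_rate$rate else breathing_rate
  if (any(rates <= 0) || any(rates > 42))
    stop("breathing_rate must lie in (0, 42] cycles/min")
  stopifnot(amp_chest >= 0, amp_abd >= 0, amp_chest <= 0.02, amp_abd <= 0.02,
            harmonic2_frac >= 0, harmonic2_frac < 1)
  if (!is.null(movement_events)) {
    stopifnot(all(movement_events$duration > 0))
    if (is.null(movement_events$limb)) movement_events$limb <- 1L
  }
  if (!is.null(asynchrony_events)) stopifnot(all(asynchrony_events$duration > 0))
  sc <- list(breathing_rate = breathing_rate, amp_chest = amp_chest,
             amp_abd = amp_abd, phase_offset = phase_offset,
             harmonic2_frac = harmonic2_frac,
             movement_events = movement_events,
             asynchrony_events = asynchrony_events)
  class(sc) <- "motion_script"
  sc
}

#' Breathing phase at given times
#'
#' Integrated breathing phase `2 pi integral f dt` for a scalar or
#' piecewise-constant rate.
#'
#' @param times Time vector in seconds.
#' @param rate Scalar rate in cycles/min or data frame `(time, rate)`.
#' @return Phase in radians at `times`.
#' @export
breathing_phase <- function(times, rate) {
  if (!is.data.frame(rate)) return(2 * pi * (rate / 60) * times)
  brk <- c(rate$time, Inf)
  f <- rate$rate / 60
  # piecewise-constant rate; exact cumulative integral per sample
  tt <- pmax(times, brk[1])
  ph <- vapply(tt, function(x) {
    tot <- 0
    for (i in seq_along(f)) {
      t1 <- brk[i]; t2 <- brk[i + 1]
      if (x <= t1) break
      tot <- tot + f[i] * (min(x, t2) - t1)
    }
    2 * pi * tot
  }, numeric(1))
  ph
}

#' Normalized breathing waveform
#'
#' `g(theta) = (sin(theta) + h2 sin(2 theta)) / gmax`, scaled so that its
#' supremum over a full cycle is exactly 1; the displacement of a breathing
#' scatterer is `amplitude * g(phase)` along its surface normal.
#'
#' @param theta Phase in radians.
#' @param harmonic2_frac Second-harmonic fraction `h2`.
#' @return Waveform values with supremum 1 over a cycle.
#' @export
breathing_waveform <- function(theta, harmonic2_frac = 0) {
  g <- sin(theta) + harmonic2_frac * sin(2 * theta)
  if (harmonic2_frac == 0) return(g)
  f <- function(x) sin(x) + harmonic2_frac * sin(2 * x)
  gr <- seq(0, 2 * pi, length.out = 2001)
  i <- which.max(f(gr))
  pk <- optimize(f, interval = gr[c(max(i - 2, 1), min(i + 2, 2001))],
                 maximum = TRUE, tol = 1e-13)
  g / pk$objective
}

# Smooth 0->1->0 activation of an asynchrony episode with raised-cosine
# transitions of `edge` seconds inside the event.
async_ramp <- function(times, events, edge = 1.5) {
  r <- numeric(length(times))
  if (is.null(events) || nrow(events) == 0) return(r)
  for (i in seq_len(nrow(events))) {
    t0 <- events$t_start[i]; t1 <- t0 + events$duration[i]
    e <- min(edge, events$duration[i] / 3)
    ri <- numeric(length(times))
    ri[times >= t0 + e & times <= t1 - e] <- 1
    up <- times >= t0 & times < t0 + e
    ri[up] <- 0.5 * (1 - cos(pi * (times[up] - t0) / e))
    dn <- times > t1 - e & times <= t1
    ri[dn] <- 0.5 * (1 - cos(pi * (t1 - times[dn]) / e))
    r <- pmax(r, ri)
  }
  r
}

#' Scatterer trajectories under a motion script
#'
#' Chest scatterers are displaced along the scene's breathing direction
#' (for full body scenes a blend of the body's anterior axis and the
#' local surface normal; for [point_scene()] the surface normal) by
#' `amp_chest * g(phase + offset)` and abdomen scatterers by
#' `amp_abd * g(phase)`, where `g` is the normalized breathing waveform and
#' the offset includes the scripted chest-abdomen phase offset plus 180
#' degrees during asynchrony episodes (with smooth transitions). Movement
#' events superimpose a raised-cosine out-and-back excursion of the stated
#' displacement on the stated region. Clutter and head are static.
#'
#' @param scene A [make_pose_scene()] scene.
#' @param script A [motion_script()].
#' @param times Uniformly sampled frame times in seconds.
#' @return List with `pos` (`T x S x 3` array of radar-frame positions),
#'   `times`, and `chest_disp`/`abd_disp` (the scripted displacement
#'   series in metres, before projection, useful as reference traces).
#' @export
scatterer_trajectories <- function(scene, script, times) {
  if (length(times) == 0) stop("empty time vector")
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9) stop("times must be uniformly sampled")
  }
  S <- nrow(scene$positions); T <- length(times)
  ph <- breathing_phase(times, script$breathing_rate)
  off <- script$phase_offset * pi / 180 +
    pi * async_ramp(times, script$asynchrony_events)
  chest_d <- script$amp_chest * breathing_waveform(ph + off, script$harmonic2_frac)
  abd_d <- script$amp_abd * breathing_waveform(ph, script$harmonic2_frac)

  # displacement magnitude per (t, s); every scatterer follows the
  # breathing series of the trunk section it belongs to (or rests on)
  follows <- if (!is.null(scene$follows)) scene$follows else scene$region
  disp <- matrix(0, T, S)
  ch <- follows == "chest"; ab <- follows == "abdomen"
  if (any(ch)) disp[, ch] <- chest_d %o% scene$breath_scale[ch]
  if (any(ab)) disp[, ab] <- abd_d %o% scene$breath_scale[ab]

  bdir <- if (!is.null(scene$breath_dir)) scene$breath_dir else scene$normals
  pos <- array(0, c(T, S, 3))
  for (k in 1:3)
    pos[, , k] <- matrix(scene$positions[, k], T, S, byrow = TRUE) +
      disp * matrix(bdir[, k], T, S, byrow = TRUE)

  ev <- script$movement_events
  if (!is.null(ev) && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      t0 <- ev$t_start[i]; du <- ev$duration[i]
      u <- (times - t0) / du
      act <- u >= 0 & u <= 1
      if (!any(act)) next
      excur <- numeric(T)
      excur[act] <- ev$displacement[i] * 0.5 * (1 - cos(2 * pi * u[act]))
      mask <- if (ev$region[i] == "limb") {
        scene$limb_id == ev$limb[i]
      } else if (ev$region[i] == "body") {
        scene$region %in% c("chest", "abdomen", "head", "limb")
      } else scene$region == ev$region[i]
      if (!any(mask)) next
      dir <- c(ev$dx[i], ev$dy[i], ev$dz[i])
      dir <- dir / sqrt(sum(dir^2))
      for (k in 1:3)
        pos[, mask, k] <- pos[, mask, k] + excur * dir[k]
    }
  }
  list(pos = pos, times = times, chest_disp = chest_d, abd_disp = abd_d)
}

#' Ground-truth labels for a simulated window
#'
#' @param scene A [make_pose_scene()] or [make_empty_scene()] scene.
#' @param script A [motion_script()].
#' @param window Length-2 numeric `(t0, t1)` in seconds.
#' @param interval Label interval in seconds (default 5).
#' @param min_overlap Minimum event-interval overlap in seconds for the
#'   interval to be labelled "with movement". The ends of a
#'   raised-cosine event carry essentially zero velocity and
#'   sub-millimetre displacement, so an overlap shorter than half the
#'   detector's smoothing window contains no physically detectable
#'   motion.
#' @return List with `presence`, `pose_class`, `joints`, `movement_labels`
#'   (data frame `t_start`, `t_end`, `label`; `label` is `TRUE` for an
#'   interval iff a movement event overlaps it by more than
#'   `min_overlap`), `rate_series` and `phase_offset_series` (1 Hz
#'   grids).
#' @export
ground_truth_labels <- function(scene, script, window, interval = 5,
                                min_overlap = 0.25) {
  stopifnot(length(window) == 2, window[2] > window[1])
  starts <- seq(window[1], window[2] - interval, by = interval)
  ev <- script$movement_events
  lab <- vapply(starts, function(s) {
    if (is.null(ev) || nrow(ev) == 0) return(FALSE)
    any(pmin(ev$t_start + ev$duration, s + interval) -
          pmax(ev$t_start, s) > min_overlap)
  }, logical(1))
  tg <- seq(window[1], window[2], by = 1)
  rate <- if (is.data.frame(script$breathing_rate)) {
    idx <- findInterval(tg, script$breathing_rate$time)
    script$breathing_rate$rate[pmax(idx, 1)]
  } else rep(script$breathing_rate, length(tg))
  pos <- script$phase_offset + 180 * async_ramp(tg, script$asynchrony_events)
  list(presence = isTRUE(scene$presence), pose_class = scene$pose_class,
       joints = scene$joints,
       movement_labels = data.frame(t_start = starts,
                                    t_end = starts + interval, label = lab),
       rate_series = data.frame(time = tg, rate = rate),
       phase_offset_series = data.frame(time = tg, offset_deg = pos))
}
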