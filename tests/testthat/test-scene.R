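test_that("pose scenes are deterministic and geometrically labeled", {
  s1 <- make_pose_scene("supine", 1.75, 0.40, seed = 1)
  s2 <- make_pose_scene("supine", 1.75, 0.40, seed = 1)
  expect_identical(s1, s2)
  expect_error(make_pose_scene("sitting", 1.75, 0.40, seed = 1),
               "unknown pose_class")
  expect_error(make_pose_scene("supine", 2.4, 0.40, seed = 1))

  # every scatterer carries exactly one region label
  expect_true(all(s1$region %in% c("chest", "abdomen", "head", "limb",
                                   "clutter")))
  expect_gte(sum(s1$region %in% c("chest", "abdomen")), 200)
  expect_gt(sum(s1$region == "chest"), 0)
  expect_gt(sum(s1$region == "abdomen"), 0)

  # supine: anterior (chest) direction points into the +z hemisphere of
  # the radar frame
  expect_gt(s1$anterior[3], 0)
  # all scatterers at positive range within the unambiguous range
  r <- sqrt(rowSums(s1$positions^2))
  expect_true(all(r > 0 & r < 2.1336))

  # lateral: body axis along the bed, anterior horizontal in the world
  sl <- make_pose_scene("lateral", 1.75, 0.40, seed = 2)
  expect_equal(abs(sl$anterior_world[3]), 0)  # within 30 deg of horizontal
  j <- sl$joints
  seg <- unlist(j[j$joint == "xiphoid", c("x", "y", "z")]) -
    unlist(j[j$joint == "navel", c("x", "y", "z")])
  # xiphoid-navel axis parallel to the bed long axis (radar x)
  expect_gt(abs(seg[1]) / sqrt(sum(seg^2)), cos(10 * pi / 180))
})

test_that("joints lie inside the padded torso hull", {
  for (pc in c("supine", "prone", "lateral")) {
    s <- make_pose_scene(pc, 1.68, 0.38, seed = 4)
    torso <- s$positions[s$region %in% c("chest", "abdomen"), ]
    for (k in 1:3) {
      expect_true(all(s$joints[[c("x", "y", "z")[k]]] >=
                        min(torso[, k]) - 0.05))
      expect_true(all(s$joints[[c("x", "y", "z")[k]]] <=
                        max(torso[, k]) + 0.05))
    }
  }
})

test_that("trajectories follow the scripted breathing kinematics", {
  # static script: all positions constant
  sc <- make_pose_scene("supine", 1.75, 0.40, seed = 1)
  scr0 <- motion_script(breathing_rate = 12, amp_chest = 0, amp_abd = 0)
  tt <- seq(0, 2, by = 0.05)
  tr0 <- scatterer_trajectories(sc, scr0, tt)
  expect_equal(max(abs(sweep(tr0$pos, c(2, 3),
                             tr0$pos[1, , ]))), 0)

  # closed-form sinusoid: abdomen displacement peak-to-peak = 2 * amp,
  # completing rate/60 * T cycles
  p <- point_scene(rbind(c(0, 1.2, 0)), region = "abdomen")
  scr <- motion_script(breathing_rate = 12, amp_chest = 0.005,
                       amp_abd = 0.005, phase_offset = 0,
                       harmonic2_frac = 0)
  tt <- seq(0, 25 - 0.05, by = 0.05)
  tr <- scatterer_trajectories(p, scr, tt)
  d <- tr$pos[, 1, 2] - p$positions[1, 2]  # along the normal (-y here)
  expect_equal(diff(range(d)), 0.010, tolerance = 1e-9)
  # exactly 5 full cycles in 25 s at 12 cycles/min: spectral line at
  # cycle index 5
  spec <- Mod(fft(d))[2:250]
  expect_equal(which.max(spec), 5)

  # displacement amplitude conservation at the analytic peak
  peak_t <- 60 / 12 / 4  # quarter period
  trp <- scatterer_trajectories(p, scr, c(0, peak_t))
  expect_equal(abs(trp$pos[2, 1, 2] - p$positions[1, 2]), 0.005,
               tolerance = 1e-9)

  # antiphase episode: chest and abdomen series have normalized inner
  # product near -1 (evaluated with the phase-shift formula)
  scr2 <- motion_script(breathing_rate = 15, amp_chest = 0.004,
                        amp_abd = 0.004, phase_offset = 0,
                        harmonic2_frac = 0,
                        asynchrony_events = data.frame(t_start = 0,
                                                       duration = 40))
  tt2 <- seq(10, 30, by = 0.05)  # fully inside the episode core
  tr2 <- scatterer_trajectories(sc, scr2, tt2)
  ip <- sum(tr2$chest_disp * tr2$abd_disp) /
    sqrt(sum(tr2$chest_disp^2) * sum(tr2$abd_disp^2))
  expect_lt(ip, -0.99)
  expect_equal(phase_shift_angle(tr2$abd_disp, tr2$chest_disp), 180,
               tolerance = 2)
})

test_that("script validation rejects out-of-band parameters", {
  expect_error(motion_script(breathing_rate = 0), "cycles/min")
  expect_error(motion_script(breathing_rate = 50), "cycles/min")
  expect_error(motion_script(harmonic2_frac = 1.2))
  expect_error(scatterer_trajectories(
    make_pose_scene("supine", 1.75, 0.4, seed = 1), motion_script(),
    numeric(0)), "empty")
})

test_that("ground-truth labels follow the interval overlap rule", {
  sc <- make_pose_scene("supine", 1.75, 0.40, seed = 1)
  scr <- motion_script()
  gt0 <- ground_truth_labels(sc, scr, c(0, 30))
  expect_false(any(gt0$movement_labels$label))
  expect_true(gt0$presence)

  ev <- data.frame(t_start = 7, duration = 3, displacement = 0.1,
                   region = "limb", limb = 1L, dx = 0, dy = 1, dz = 0)
  scr1 <- motion_script(movement_events = ev)
  gt1 <- ground_truth_labels(sc, scr1, c(0, 30))
  expect_equal(gt1$movement_labels$label, c(FALSE, TRUE, FALSE, FALSE,
                                            FALSE, FALSE))

  # piecewise rate steps at the scripted time
  scr2 <- motion_script(breathing_rate = data.frame(time = c(0, 60),
                                                    rate = c(12, 18)))
  gt2 <- ground_truth_labels(sc, scr2, c(0, 120))
  expect_equal(gt2$rate_series$rate[gt2$rate_series$time < 60][1], 12)
  expect_equal(tail(gt2$rate_series$rate, 1), 18)
  ph <- breathing_phase(c(30, 60, 90), data.frame(time = c(0, 60),
                                                  rate = c(12, 18)))
  expect_equal(ph, 2 * pi * c(0.2 * 30, 0.2 * 60, 0.2 * 60 + 0.3 * 30))
})
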