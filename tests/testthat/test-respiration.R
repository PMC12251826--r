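test_that("torso partition splits chest from abdomen at the bisector", {
  cfg <- radar_config("desk", n_rx = 20, n_tx = 20, n_fft_u = 48,
                      n_fft_v = 48, n_phi = 15, n_theta = 19)
  sc <- make_pose_scene("supine", 1.75, 0.40, seed = 3)
  masks <- partition_torso(sc$joints, cfg$grid)
  expect_false(any(masks$chest & masks$abdomen))
  expect_gt(sum(masks$chest), 0)
  expect_gt(sum(masks$abdomen), 0)

  # chest mask cells sit on the xiphoid side in azimuth
  ax <- angle_axes(cfg$grid)
  j <- sc$joints
  mid <- (j$phi[j$joint == "xiphoid"] + j$phi[j$joint == "navel"]) / 2
  sgn <- sign(j$phi[j$joint == "xiphoid"] - mid)
  expect_true(all(sign(ax$phi[row(masks$chest)[masks$chest]] - mid) == sgn))

  # swapping shoulder and hip labels flips the masks
  sw <- sc$joints
  sw$joint <- sw$joint[c(1, 2, 5, 6, 3, 4)]
  m2 <- partition_torso(sw, cfg$grid)
  expect_identical(m2$chest, masks$abdomen)
  expect_identical(m2$abdomen, masks$chest)

  deg <- sc$joints
  deg[deg$joint == "navel", c("phi", "theta")] <-
    deg[deg$joint == "xiphoid", c("phi", "theta")]
  expect_error(partition_torso(deg, cfg$grid), "degenerate")

  # chest mask covers most chest-scatterer cells
  r <- sqrt(rowSums(sc$positions^2))
  ph <- asin(sc$positions[, 1] / r)
  th <- asin(sc$positions[, 3] / r)
  ch <- sc$region == "chest"
  guard <- 0.72 * cfg$waveform$lambda0 / (cfg$geometry$M * cfg$geometry$d_rx)
  far_side <- abs(ph - mid) > guard + 0.03  # clear of the guard band
  kc <- vapply(which(ch & far_side & ph > mid), function(i) {
    ku <- which.min(abs(ax$phi - ph[i]))
    kv <- which.min(abs(ax$theta - th[i]))
    masks$chest[ku, kv]
  }, logical(1))
  expect_gt(mean(kc), 0.8)
})

test_that("region displacement is the amplitude-weighted filtered mean", {
  fs <- 20; T <- 600
  t <- (0:(T - 1)) / fs
  s <- sin(2 * pi * 0.25 * t)
  # all cells identical: weights cancel (zero-mean input so the slow
  # high-pass edge transient of the zero-phase filter does not reach
  # into the compared span)
  zeta <- array(rep(s, 4), c(T, 2, 2))
  merged <- list(zeta = zeta, abar = matrix(c(1, 2, 3, 4), 2, 2),
                 times = t, frame_rate = fs,
                 grid = radar_config("desk")$grid)
  tr <- region_displacement(merged, matrix(TRUE, 2, 2))
  expect_equal(as.numeric(tr[200:400]), s[200:400], tolerance = 0.02)

  # two cells, amplitudes 3:1, opposite-sign sinusoids: the weighted
  # mean is half the stronger one
  zeta2 <- array(0, c(T, 2, 1))
  zeta2[, 1, 1] <- s; zeta2[, 2, 1] <- -s
  merged2 <- list(zeta = zeta2, abar = matrix(c(3, 1), 2, 1), times = t,
                  frame_rate = fs, grid = merged$grid)
  tr2 <- region_displacement(merged2, matrix(TRUE, 2, 1))
  expect_equal(as.numeric(tr2[200:400]), 0.5 * s[200:400],
               tolerance = 0.02)
  expect_error(region_displacement(merged2, matrix(FALSE, 2, 1)),
               "empty")
})

test_that("rate estimation finds the fundamental by harmonic summation", {
  fs <- 20
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  pure <- sin(2 * pi * 0.2 * t)
  rs <- breathing_rate(pure, fs)
  expect_true(all(rs$quality))
  expect_lt(max(abs(rs$rate_cpm - 12)), 0.75)

  # strong second harmonic: a plain spectral argmax locks onto the
  # octave, the harmonic sum does not
  harm <- 0.6 * sin(2 * pi * 0.2 * t) + sin(2 * pi * 0.4 * t)
  naive <- breathing_rate(harm, fs, n_harmonics = 1)
  hsum <- breathing_rate(harm, fs, n_harmonics = 3)
  expect_gt(max(abs(naive$rate_cpm - 12)), 5)   # octave error
  expect_lt(max(abs(hsum$rate_cpm - 12)), 0.75)

  # featureless trace: flagged, no rate
  flat <- breathing_rate(rep(1, length(t)), fs)
  expect_false(any(flat$quality))
  expect_true(all(is.na(flat$rate_cpm)))
  expect_error(breathing_rate(pure[1:100], fs), "shorter")
})

test_that("the phase-shift angle behaves like a phase difference", {
  fs <- 20
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  a <- sin(2 * pi * 0.2 * t)
  expect_equal(phase_shift_angle(a, a), 0)
  expect_equal(phase_shift_angle(a, -a), 180)
  # integer periods, 90 degree offset: orthogonal
  b <- sin(2 * pi * 0.2 * t + pi / 2)
  expect_equal(phase_shift_angle(a, b), 90, tolerance = 1e-6)

  # non-integer periods at 45 degrees: direct numerical evaluation
  t2 <- seq(0, 15 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t2); y <- sin(2 * pi * 0.25 * t2 + pi / 4)
  ref <- acos(sum(x * y) / sqrt(sum(x^2) * sum(y^2))) * 180 / pi
  expect_equal(phase_shift_angle(x, y), ref)
  expect_lt(abs(ref - 45), 3)

  # symmetry and invariance to positive scaling
  expect_equal(phase_shift_angle(x, y), phase_shift_angle(y, x))
  expect_equal(phase_shift_angle(3.7 * x, y), phase_shift_angle(x, y))
  expect_error(phase_shift_angle(0 * x, y), "zero-norm")

  ser <- phase_shift_series(rep(a, 4), rep(b, 4), fs)
  expect_true(all(abs(ser$theta_deg - 90) < 1))
})
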