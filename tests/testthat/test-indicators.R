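test_that("phase unwrapping removes 2 pi jumps", {
  expect_equal(unwrap_phase(rep(0.3, 10)), rep(0.3, 10))
  ramp <- seq(0, 12, by = 0.4)
  wrapped <- Arg(exp(1i * ramp))
  expect_equal(unwrap_phase(wrapped), ramp, tolerance = 1e-12)
})

test_that("a breathing scatterer's phase swing matches the two-way law", {
  # peak-to-peak displacement d gives a phase swing of 4 pi d / lambda0:
  # 5 mm at 65.5 GHz -> about 13.7 rad
  cfg <- radar_config("desk")
  p <- point_scene(rbind(c(0, 1.1, 0)))
  scr <- motion_script(breathing_rate = 12, amp_chest = 0.0025,
                       amp_abd = 0.0025, phase_offset = 0,
                       harmonic2_frac = 0)
  rec <- simulate_recording(p, scr, 25, cfg, seed = 1)
  w <- rec$windows[[1]]
  pk <- which(w$abar == max(w$abar), arr.ind = TRUE)
  z <- unwrapped_phase(w, pk[1], pk[2])
  expect_equal(diff(range(z)), 4 * pi * 0.005 / cfg$waveform$lambda0,
               tolerance = 0.02)
})

test_that("alpha indicators match an independent spectral computation", {
  # scripted sinusoidal-phase cell plus noise-like cells
  fs <- 20; T <- 500
  t <- (0:(T - 1)) / fs
  set.seed(3)
  nphi <- 4; nth <- 3
  values <- array(complex(modulus = 1,
                          argument = runif(T * nphi * nth, -0.02, 0.02)),
                  c(T, nphi, nth))
  zeta_scripted <- 1.5 * sin(2 * pi * 0.25 * t) - 2
  values[, 2, 2] <- 3 * exp(1i * zeta_scripted)
  rw <- synthetic_reduced(values)
  maps <- compute_indicators(rw, a_ts_db = 6)

  # independent computation: direct DFT sums, same conventions
  zeta <- unwrap_phase(Arg(values[, 2, 2]))
  nu <- (1:(T / 2)) * fs / T
  mag <- vapply(seq_along(nu), function(k) {
    Mod(sum(zeta * exp(-2i * pi * k * (0:(T - 1)) / T)))
  }, numeric(1))
  p <- mag / sum(mag)
  inb <- nu >= 0.09 & nu <= 0.70
  expect_equal(maps$az_el$alpha1[2, 2], mean(p[inb]), tolerance = 1e-9)
  expect_equal(maps$az_el$alpha2[2, 2], max(p[inb]), tolerance = 1e-9)
  expect_gte(maps$az_el$alpha2[2, 2], maps$az_el$alpha1[2, 2])
  expect_lte(maps$az_el$alpha2[2, 2], 1)
})

test_that("static cells give zero range spread and the static range", {
  fs <- 20; T <- 200
  values <- array(1.0 + 0i, c(T, 3, 3))
  rw <- synthetic_reduced(values)
  rw$rma[] <- rw$grid$r_axis[5]
  maps <- compute_indicators(rw, a_ts_db = 0)
  expect_equal(max(abs(maps$az_el$beta1)), 0)
  expect_equal(unique(as.vector(maps$az_el$beta2)), rw$grid$r_axis[5])
  # constant phase: no in-band energy
  expect_lt(max(maps$az_el$alpha2), 1e-9)
})

test_that("the amplitude floor substitutes failing cells with the minimum", {
  fs <- 20; T <- 400
  t <- (0:(T - 1)) / fs
  values <- array(0.01 + 0i, c(T, 5, 5))
  for (k in 2:4) for (l in 2:4)
    values[, k, l] <- (1 + 0.1 * k) * exp(1i * 0.5 * sin(2 * pi * 0.2 * t + k + l))
  rw <- synthetic_reduced(values)
  set.seed(9)
  rw$rma <- array(sample(rw$grid$r_axis[1:6], T * 25, replace = TRUE),
                  c(T, 5, 5))
  maps <- compute_indicators(rw, a_ts_db = 10)
  expect_false(all(maps$pass))
  for (nm in names(maps$az_el)) {
    m <- maps$az_el[[nm]]
    expect_equal(min(m), min(m[maps$pass]))
    expect_equal(unique(as.vector(m[!maps$pass])), min(m[maps$pass]))
  }
  expect_error(compute_indicators(rw, a_ts_db = 80), "no cell passes")
})

test_that("heatmaps are per-channel standardized with reference shapes", {
  # synthetic reduced window on the full-size grid
  cfg <- radar_config("full")
  T <- 50
  set.seed(5)
  n <- T * cfg$grid$n_phi * cfg$grid$n_theta
  values <- array(complex(real = rnorm(n, 1), imaginary = rnorm(n, 0, 0.2)),
                  c(T, cfg$grid$n_phi, cfg$grid$n_theta))
  rw <- synthetic_reduced(values, grid = cfg$grid)
  rw$amean <- array(runif(cfg$grid$n_r * cfg$grid$n_phi * cfg$grid$n_theta),
                    c(cfg$grid$n_r, cfg$grid$n_phi, cfg$grid$n_theta))
  rw$rma <- array(sample(cfg$grid$r_axis, n, replace = TRUE),
                  c(T, cfg$grid$n_phi, cfg$grid$n_theta))
  rw$jma <- matrix(sample(seq_len(cfg$grid$n_r),
                          cfg$grid$n_phi * cfg$grid$n_theta, replace = TRUE),
                   cfg$grid$n_phi, cfg$grid$n_theta)
  maps <- compute_indicators(rw, a_ts_db = 0)
  hm <- to_heatmaps(maps)
  expect_equal(dim(hm$az_el), c(5, 17, 25))
  expect_equal(dim(hm$el_dist), c(5, 25, 72))
  for (ch in 1:5) {
    expect_lt(abs(mean(hm$az_el[ch, , ])), 1e-10)
    expect_equal(sd(hm$az_el[ch, , ]), 1, tolerance = 1e-6)
  }
  # constant channel maps to zeros
  maps$az_el$abar[] <- 3
  hm2 <- to_heatmaps(maps)
  expect_true(all(hm2$az_el[1, , ] == 0))
})

test_that("stronger breathing displacement does not lower alpha2", {
  fs <- 20; T <- 400
  t <- (0:(T - 1)) / fs
  set.seed(21)
  drift <- cumsum(rnorm(T, 0, 0.05))  # fixed out-of-band disturbance
  a2 <- vapply(c(0.5, 1, 2, 4), function(amp) {
    values <- array(complex(modulus = 1,
                            argument = rep(0.01, T * 9)), c(T, 3, 3))
    values[, 2, 2] <- exp(1i * (amp * sin(2 * pi * 0.3 * t) + drift))
    maps <- compute_indicators(synthetic_reduced(values), a_ts_db = 0)
    maps$az_el$alpha2[2, 2]
  }, numeric(1))
  expect_true(all(diff(a2) >= -1e-9))
})
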