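#' Aspect-dependent scatterer weights
#'
#' Microwave reflection off skin is strongly specular, while the signal
#' model assumes isotropic elements, so directivity is folded into the
#' reflection coefficient: each scatterer's reflectivity is weighted by
#' `max(0, cos(angle))^exponent`, where the angle is between the local
#' surface normal and the scatterer-to-array-centre direction.
#' `exponent = 0` gives isotropic scattering.
#'
#' @param scene A `body_scene`.
#' @param pos `T x S x 3` positions from [scatterer_trajectories()].
#' @param exponent Cosine power (default 4).
#' @return `T x S` matrix of nonnegative weights.
#' @export
view_weights <- function(scene, pos, exponent = 4) {
  T <- dim(pos)[1]; S <- dim(pos)[2]
  r <- sqrt(pos[, , 1]^2 + pos[, , 2]^2 + pos[, , 3]^2)
  if (exponent == 0)
    return(matrix(scene$reflectivity, T, S, byrow = TRUE))
  cosang <- -(pos[, , 1] * matrix(scene$normals[, 1], T, S, byrow = TRUE) +
              pos[, , 2] * matrix(scene$normals[, 2], T, S, byrow = TRUE) +
              pos[, , 3] * matrix(scene$normals[, 3], T, S, byrow = TRUE)) / r
  w <- pmax(cosang, 0)^exponent
  w * matrix(scene$reflectivity, T, S, byrow = TRUE)
}

#' Simulate raw SFCW MIMO data for scatterer trajectories
#'
#' Evaluates the exact bistatic received-signal model: each sample is the
#' coherent sum over scatterers of
#' `w * exp(-j k_f (Rt + Rr)) / (16 pi^2 Rt Rr)` with the exact TX and RX
#' distances at the frame's scatterer positions and the frequency-dependent
#' wavenumber `k_f` (the simulator is deliberately stricter than the
#' far-field model the imaging assumes). TX multiplexing is modelled as
#' ideal.
#'
#' @param trajectories Output of [scatterer_trajectories()], or any list
#'   with `pos` (`T x S x 3`) and `times`.
#' @param weights `T x S` nonnegative weight matrix (reflectivity times
#'   aspect factor), e.g. from [view_weights()].
#' @param geometry An [array_geometry()].
#' @param waveform An [sfcw_waveform()].
#' @param snr_db Per-sample SNR of added complex white noise; `Inf`
#'   (default) adds none.
#' @param seed Seed for the noise realization.
#' @return A `raw_cube` object: complex `samples[t, l, m, n]`, `times`, and
#'   provenance.
#' @export
simulate_raw <- function(trajectories, weights, geometry, waveform,
                         snr_db = Inf, seed = NULL) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(waveform, "sfcw_waveform"))
  pos <- trajectories$pos
  stopifnot(length(dim(pos)) == 3, dim(pos)[3] == 3)
  stopifnot(all(dim(weights) == dim(pos)[1:2]))
  samples <- simulate_raw_cpp(pos, weights, geometry$rx_x, geometry$tx_z,
                              frequency_grid(waveform), C0)
  cube <- list(samples = samples, times = trajectories$times,
               geometry = geometry, waveform = waveform,
               snr_db = snr_db, seed = seed)
  class(cube) <- "raw_cube"
  if (is.finite(snr_db)) cube <- add_noise(cube, snr_db, seed)
  cube
}

#' Add circularly symmetric complex Gaussian noise to a raw cube
#'
#' Noise power is scaled so that mean signal power over all samples divided
#' by noise power equals `10^(snr_db / 10)`.
#'
#' @param cube A `raw_cube`.
#' @param snr_db Target SNR in dB; `Inf` returns the cube unchanged.
#' @param seed Seed for reproducibility.
#' @return The noisy `raw_cube`.
#' @export
add_noise <- function(cube, snr_db, seed = NULL) {
  stopifnot(inherits(cube, "raw_cube"))
  if (is.infinite(snr_db) && snr_db > 0) return(cube)
  s <- cube$samples
  psig <- mean(Mod(s)^2)
  if (psig == 0) stop("cannot set an SNR on an all-zero cube")
  pn <- psig / 10^(snr_db / 10)
  if (!is.null(seed)) set.seed(seed)
  n <- length(s)
  noise <- complex(real = rnorm(n, 0, sqrt(pn / 2)),
                   imaginary = rnorm(n, 0, sqrt(pn / 2)))
  dim(noise) <- dim(s)
  cube$samples <- s + noise
  cube$snr_db <- snr_db
  cube
}
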