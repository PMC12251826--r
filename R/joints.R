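#' Torso joint set
#'
#' Six named torso joints (xiphoid, navel, left/right shoulder, left/right
#' hip) in radar polar coordinates `(r, phi, theta)` and the derived
#' Cartesian coordinates `x = r cos(theta) sin(phi)`,
#' `y = r cos(theta) cos(phi)`, `z = r sin(theta)` (y is boresight).
#'
#' @param r,phi,theta Numeric vectors of length 6 (metres / radians), in
#'   the order xiphoid, navel, left_shoulder, right_shoulder, left_hip,
#'   right_hip.
#' @return A data frame of class `joint_set` with columns `joint`, `r`,
#'   `phi`, `theta`, `x`, `y`, `z`.
#' @export
joint_set <- function(r, phi, theta) {
  stopifnot(length(r) == 6, length(phi) == 6, length(theta) == 6,
            all(r > 0))
  js <- data.frame(joint = JOINT_NAMES, r = r, phi = phi, theta = theta,
                   x = r * cos(theta) * sin(phi),
                   y = r * cos(theta) * cos(phi),
                   z = r * sin(theta))
  class(js) <- c("joint_set", "data.frame")
  js
}

JOINT_NAMES <- c("xiphoid", "navel", "left_shoulder", "right_shoulder",
                 "left_hip", "right_hip")

#' Joint set from Cartesian radar-frame coordinates
#'
#' @param xyz 6 x 3 matrix of radar-frame coordinates (rows in the standard
#'   joint order).
#' @return A [joint_set()].
#' @export
joint_set_from_xyz <- function(xyz) {
  stopifnot(nrow(xyz) == 6, ncol(xyz) == 3)
  r <- sqrt(rowSums(xyz^2))
  theta <- asin(xyz[, 3] / r)
  phi <- asin(pmin(pmax(xyz[, 1] / (r * cos(theta)), -1), 1))
  joint_set(r, phi, theta)
}

#' Mean angular error between two joint sets (degrees)
#'
#' The loss used for joint regression: the mean absolute angle between the
#' lines connecting the radar (origin) to the true and the predicted
#' position, averaged over the six joints. Computed with the
#' `atan2(|cross|, dot)` form for numerical stability near zero angle.
#'
#' @param true,pred [joint_set()] objects (or lists of equal length; the
#'   batch mean is returned).
#' @return Mean angle in degrees.
#' @export
angular_loss <- function(true, pred) {
  if (!inherits(true, "joint_set") && is.list(true)) {
    stopifnot(length(true) == length(pred))
    return(mean(mapply(angular_loss, true, pred)))
  }
  a <- as.matrix(true[, c("x", "y", "z")])
  b <- as.matrix(pred[, c("x", "y", "z")])
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-length joint vector")
  a <- a / na; b <- b / nb
  d <- rowSums(a * b)
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  ang <- atan2(sqrt(rowSums(cr^2)), d)
  mean(ang) * 180 / pi
}

#' Per-joint mean absolute x-z plane localization error (cm)
#'
#' The evaluation metric for joint regression: for each joint, the mean
#' over samples of the Euclidean distance between true and predicted
#' locations projected on the radar x-z plane.
#'
#' @param true,pred Lists of [joint_set()] objects of equal length.
#' @return Named numeric vector, one MAE in centimetres per joint.
#' @export
xz_mae <- function(true, pred) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  errs <- sapply(seq_along(true), function(i) {
    sqrt((true[[i]]$x - pred[[i]]$x)^2 + (true[[i]]$z - pred[[i]]$z)^2)
  })
  out <- rowMeans(errs) * 100
  names(out) <- JOINT_NAMES
  out
}
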