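# Whole-cloud augmentations. All operate on a normalized cloud (z in [0,1],
# x/y zero-centered) and are pure: input cloud untouched, fresh cloud out.
# None of them re-normalizes its output — translation and scaling effects
# are intentional and must survive.

#' Jitter point positions with Gaussian noise
#'
#' Adds i.i.d. noise `N(0, sigma)` to every coordinate of every point,
#' emulating sensor noise. `sigma` is in height-normalized units, so 0.05 on
#' a 657 mm plant corresponds to 32.8 mm of noise in raw coordinates.
#' Normals, colors and labels are unchanged.
#'
#' @param cloud a normalized `plant_cloud`.
#' @param sigma noise standard deviation (>= 0), normalized units.
#' @param seed optional integer seed.
#' @return the jittered `plant_cloud`.
#' @export
augment_jitter <- function(cloud, sigma, seed = NULL) {
  stopifnot_scalar_number(sigma, "sigma", lower = 0)
  require_normalized(cloud)
  n <- n_points(cloud)
  eps <- with_seed_maybe(seed, matrix(stats::rnorm(3L * n, 0, sigma), n, 3L))
  out <- cloud
  out$positions <- cloud$positions + eps
  out
}

#' Scale the cloud in x and y
#'
#' Multiplies x by `eta_x` and y by `eta_y`, each drawn independently from
#' `U(a, b)`, to vary plant girth. z is untouched: the normalization already
#' fixes the height unit, so only the horizontal extent is varied.
#'
#' @param cloud a normalized `plant_cloud`.
#' @param range `(a, b)` of the uniform scale distribution, `0 < a <= b`.
#' @param seed optional integer seed.
#' @param eta optional length-2 `(eta_x, eta_y)` override for deterministic
#'   use; skips the random draw.
#' @return the scaled `plant_cloud`.
#' @export
augment_scale_xy <- function(cloud, range = c(0.5, 1.5), seed = NULL,
                             eta = NULL) {
  require_normalized(cloud)
  if (is.null(eta)) {
    check_range(range, "range", positive = TRUE)
    eta <- with_seed_maybe(seed, stats::runif(2L, range[1], range[2]))
  }
  out <- cloud
  out$positions <- cbind(cloud$positions[, 1] * eta[1],
                         cloud$positions[, 2] * eta[2],
                         cloud$positions[, 3])
  structure_drawn(out, list(eta_x = eta[1], eta_y = eta[2]))
}

#' Rotate the whole cloud
#'
#' Applies `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)` about the origin (the
#' plant center at soil level for a normalized cloud). `gamma ~ U(0, 360)`
#' randomizes the plant's turntable orientation; `alpha, beta ~ N(0,
#' sigma_r)` lean the stem slightly, as real stems incline. Normals are
#' rotated by the same matrix (rotation is the one rigid motion with a
#' defined action on normals).
#'
#' @param cloud a normalized `plant_cloud`.
#' @param sigma_r standard deviation (degrees) of the x/y-axis lean angles.
#' @param gamma_range range (degrees) for the uniform z rotation.
#' @param seed optional integer seed.
#' @param angles optional `(alpha, beta, gamma)` degrees override.
#' @return the rotated `plant_cloud`.
#' @export
augment_rotate_global <- function(cloud, sigma_r = 1, gamma_range = c(0, 360),
                                  seed = NULL, angles = NULL) {
  require_normalized(cloud)
  if (is.null(angles)) {
    stopifnot_scalar_number(sigma_r, "sigma_r", lower = 0)
    check_range(gamma_range, "gamma_range")
    angles <- with_seed_maybe(seed, c(stats::rnorm(2L, 0, sigma_r),
                                      stats::runif(1L, gamma_range[1],
                                                   gamma_range[2])))
  }
  R <- rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
  out <- cloud
  out$positions <- cloud$positions %*% t(R)
  out$normals <- cloud$normals %*% t(R)
  structure_drawn(out, list(alpha = angles[1], beta = angles[2],
                            gamma = angles[3]))
}

#' Translate the whole cloud
#'
#' Adds one offset vector `delta` per cloud, its three components drawn
#' i.i.d. from `U(a, b)` (normalized units, i.e. proportional to plant
#' height), to vary the plant's position in the scene.
#'
#' @param cloud a normalized `plant_cloud`.
#' @param range `(a, b)` of the uniform offset distribution.
#' @param seed optional integer seed.
#' @param delta optional length-3 offset override.
#' @return the translated `plant_cloud`.
#' @export
augment_translate_global <- function(cloud, range = c(-0.05, 0.05),
                                     seed = NULL, delta = NULL) {
  require_normalized(cloud)
  if (is.null(delta)) {
    check_range(range, "range")
    delta <- with_seed_maybe(seed, stats::runif(3L, range[1], range[2]))
  }
  out <- cloud
  out$positions <- sweep(cloud$positions, 2L, delta, `+`)
  structure_drawn(out, list(delta_x = delta[1], delta_y = delta[2],
                            delta_z = delta[3]))
}

#' Crop the cloud to a shrunken bounding box
#'
#' Draws `phi ~ U(a, b)` and keeps point i iff
#' `x_i` in `[(1-phi) min(x), (1-phi) max(x)]`,
#' `y_i` in `[(1-phi) min(y), (1-phi) max(y)]` and
#' `z_i` in `[0, (1-phi) max(z)]` (closed intervals), emulating a plant
#' partially cut off by the imaging volume. Because cropping removes points,
#' the result is immediately re-down-sampled (online mode) to `n_target` to
#' honor the fixed-size contract of the network input.
#'
#' @param cloud a `plant_cloud` zero-centered in x, y with z >= 0 (raw or
#'   normalized).
#' @param range `(a, b)` with `0 <= a <= b < 1`.
#' @param n_target output point count after re-down-sampling.
#' @param seed optional integer seed (governs both the crop draw and the
#'   re-down-sampling).
#' @param phi optional fixed crop fraction override.
#' @return a cropped `plant_cloud` with exactly `n_target` points.
#' @export
augment_crop <- function(cloud, range = c(0, 0.15), n_target = 50000L,
                         seed = NULL, phi = NULL) {
  run <- function() {
    if (is.null(phi)) {
      check_range(range, "range")
      if (range[1] < 0 || range[2] >= 1) stop("crop range must lie in [0, 1)")
      phi <- stats::runif(1L, range[1], range[2])
    }
    p <- cloud$positions
    keep <- crop_mask(p, phi)
    if (!any(keep)) stop("empty crop: no points survive phi = ",
                         format(phi))
    out <- downsample_cloud(cloud_subset(cloud, which(keep)), n_target,
                            mode = "online")
    structure_drawn(out, list(phi = phi))
  }
  with_seed_maybe(seed, run())
}

# Eq-style closed-interval box membership used by the crop.
crop_mask <- function(p, phi) {
  s <- 1 - phi
  p[, 1] >= s * min(p[, 1]) & p[, 1] <= s * max(p[, 1]) &
    p[, 2] >= s * min(p[, 2]) & p[, 2] <= s * max(p[, 2]) &
    p[, 3] >= 0 & p[, 3] <= s * max(p[, 3])
}

#' Adjust the brightness of all color channels
#'
#' Multiplies all 45 RGB channels of every point by one factor
#' `eta ~ U(a, b)`, emulating a change in illumination. No clipping is
#' applied: clipping would destroy the constant channel ratios the
#' multiplicative model creates, so colors may exceed 1 afterwards (they
#' stay >= 0).
#'
#' @param cloud a `plant_cloud`.
#' @param range `(a, b)` of the uniform brightness factor, `a > 0`.
#' @param seed optional integer seed.
#' @param eta optional fixed factor override.
#' @return the brightness-adjusted `plant_cloud`.
#' @export
augment_brightness <- function(cloud, range = c(0.5, 3.0), seed = NULL,
                               eta = NULL) {
  if (is.null(eta)) {
    check_range(range, "range", positive = TRUE)
    eta <- with_seed_maybe(seed, stats::runif(1L, range[1], range[2]))
  }
  out <- cloud
  out$colors <- cloud$colors * eta
  structure_drawn(out, list(eta = eta))
}

require_normalized <- function(cloud) {
  if (!isTRUE(cloud$meta$normalized)) {
    stop("this augmentation expects a normalized cloud; ",
         "call normalize_cloud() first")
  }
  invisible(cloud)
}

# Attach the randomly drawn parameter values so pipelines can log them.
structure_drawn <- function(cloud, drawn) {
  attr(cloud, "drawn") <- drawn
  cloud
}
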