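#' Normalize a raw point cloud to height units
#'
#' Zero-centers x and y, shifts z so its minimum is 0, and scales all three
#' coordinates by one isotropic factor `1 / (max(z) - min(z))` so that z
#' spans exactly `[0, 1]`. One height-based unit keeps the cloud's aspect
#' ratio intact, so that e.g. a positional offset of 0.1 always means one
#' tenth of the plant's height. Normals are re-normalized to unit length and
#' colors are brought into `[0, 1]` (8-bit encodings are divided by 255).
#' The applied offsets and scale are recorded in `meta` so the map is
#' invertible via [denormalize_cloud()].
#'
#' @param cloud a raw (unnormalized) `plant_cloud`.
#' @return a normalized `plant_cloud` with `meta$normalized = TRUE`,
#'   `meta$height_scale` = plant height in mm, `meta$xy_offset` and
#'   `meta$z_offset` the subtracted offsets in mm.
#' @seealso [denormalize_cloud()], [assemble_features()]
#' @export
normalize_cloud <- function(cloud) {
  validate_cloud(cloud)
  if (isTRUE(cloud$meta$normalized)) {
    stop("cloud is already normalized")
  }
  p <- cloud$positions
  zmin <- min(p[, 3])
  zmax <- max(p[, 3])
  if (zmax - zmin <= 0) stop("flat cloud: all z equal, cannot normalize")
  h <- zmax - zmin
  xy_off <- c(mean(p[, 1]), mean(p[, 2]))
  q <- cbind((p[, 1] - xy_off[1]) / h,
             (p[, 2] - xy_off[2]) / h,
             (p[, 3] - zmin) / h)
  nrm <- cloud$normals / sqrt(rowSums(cloud$normals^2))
  cols <- cloud$colors
  if (max(cols) > 1) cols <- cols / 255
  meta <- cloud$meta
  meta$normalized <- TRUE
  meta$height_scale <- h
  meta$xy_offset <- xy_off
  meta$z_offset <- zmin
  plant_cloud(q, nrm, cols, cloud$semantic, cloud$instance, meta)
}

#' Invert the normalization of a cloud
#'
#' Maps positions back to raw millimetre coordinates using the scale and
#' offsets recorded by [normalize_cloud()].
#'
#' @param cloud a normalized `plant_cloud`.
#' @return a raw `plant_cloud` (`meta$normalized = FALSE`).
#' @export
denormalize_cloud <- function(cloud) {
  if (!isTRUE(cloud$meta$normalized)) stop("cloud is not normalized")
  h <- cloud$meta$height_scale
  if (!is.finite(h)) stop("missing height_scale metadata")
  p <- cloud$positions
  q <- cbind(p[, 1] * h + cloud$meta$xy_offset[1],
             p[, 2] * h + cloud$meta$xy_offset[2],
             p[, 3] * h + cloud$meta$z_offset)
  meta <- cloud$meta
  meta$normalized <- FALSE
  plant_cloud(q, cloud$normals, cloud$colors, cloud$semantic, cloud$instance,
              meta)
}

#' Down-sample a cloud to a fixed number of points
#'
#' Draws a uniform random subset of `n_target` points without replacement
#' (with replacement when the source is smaller than the target, which can
#' happen after aggressive cropping, so that the fixed-size contract always
#' holds). In `"offline"` mode the sample is reproducible from `seed`; in
#' `"online"` mode a fresh sample is drawn from the ambient RNG stream on
#' every call, which is the behaviour used between training batches.
#'
#' @param cloud a `plant_cloud`.
#' @param n_target number of points to keep (>= 1).
#' @param mode `"offline"` (seeded, reproducible) or `"online"` (fresh draw
#'   per call).
#' @param seed integer seed, required in offline mode; ignored in online
#'   mode.
#' @return a `plant_cloud` with exactly `n_target` points.
#' @export
downsample_cloud <- function(cloud, n_target, mode = c("offline", "online"),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(n_target, "n_target", lower = 1)
  n <- n_points(cloud)
  if (n < 1L) stop("cannot down-sample an empty cloud")
  if (mode == "offline" && is.null(seed)) {
    stop("offline down-sampling requires a seed for reproducibility")
  }
  draw <- function() {
    sample.int(n, size = n_target, replace = n < n_target)
  }
  idx <- if (mode == "offline") with_seed_maybe(seed, draw()) else draw()
  cloud_subset(cloud, idx)
}

#' Assemble the n x 51 network feature matrix
#'
#' Stacks, per point, the normalized position (3), the unit surface normal
#' (3) and the camera-major RGB colors of the 15 cameras (45) into the
#' 51-column matrix consumed by a point-based segmentation network.
#'
#' @param cloud a normalized `plant_cloud`.
#' @return a numeric matrix with `n_points(cloud)` rows and exactly 51
#'   columns, with attribute `point_order` mapping rows to source points.
#' @export
assemble_features <- function(cloud) {
  if (!isTRUE(cloud$meta$normalized)) {
    stop("features are assembled from a normalized cloud; ",
         "call normalize_cloud() first")
  }
  m <- cbind(cloud$positions, cloud$normals, cloud$colors)
  stopifnot(ncol(m) == 51L)
  attr(m, "point_order") <- seq_len(nrow(m))
  m
}
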