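# Per-leaf geometry: base point, principal axis, phyllotactic orientation
# and rank. These descriptors anchor every leaf-level augmentation.
#
# The base point is found as the leaf point nearest to the main-stem point
# set, and the leaf axis as the first principal component of the leaf's
# stemwork (petiole/rachis) points, oriented base -> tip. Both are validated
# against synthetic ground truth in the test suite.

leaf_point_indices <- function(cloud, leaf_id) {
  which(cloud$instance == paste0("LEAF_", leaf_id))
}

# Chunked min-distance: for each row of `a`, the nearest row of `b` and the
# distance to it. Chunking keeps the n_a x n_b distance block in bounded
# memory for large clouds.
nearest_in_set <- function(a, b, chunk = 2000L) {
  n <- nrow(a)
  best_d2 <- numeric(n)
  best_j <- integer(n)
  bb <- rowSums(b^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), bb, `+`) -
      2 * (a[idx, , drop = FALSE] %*% t(b))
    best_j[idx] <- max.col(-d2, ties.method = "first")
    best_d2[idx] <- d2[cbind(seq_along(idx), best_j[idx])]
  }
  list(index = best_j, dist = sqrt(pmax(best_d2, 0)))
}

#' Detect the base point of a leaf
#'
#' Returns the position of the leaf point closest to the main-stem point set
#' (instance `STEM`) — the attachment of the petiole to the stem.
#' Deterministic: ties are broken by the lowest point index.
#'
#' @param cloud a `plant_cloud` with a `STEM` instance.
#' @param leaf_id integer leaf instance id k (points labeled `LEAF_k`).
#' @return named numeric length-3 position, with attribute `point_index`
#'   (index of the chosen point in the cloud).
#' @export
detect_base_point <- function(cloud, leaf_id) {
  li <- leaf_point_indices(cloud, leaf_id)
  if (!length(li)) stop("leaf LEAF_", leaf_id, " has no points")
  si <- which(cloud$instance == "STEM")
  if (!length(si)) stop("cloud has no main-stem (STEM) points")
  nn <- nearest_in_set(cloud$positions[li, , drop = FALSE],
                       cloud$positions[si, , drop = FALSE])
  best <- li[which.min(nn$dist)]
  structure(cloud$positions[best, ], point_index = best)
}

#' Principal axis of a leaf
#'
#' First principal component of the leaf's stemwork points (semantic
#' `STEMWORK` within instance `LEAF_k`), i.e. of the petiole/rachis
#' skeleton. If fewer than 3 such points exist (sparse petioles near the
#' plant top) all leaf points are used instead. The sign is chosen so the
#' axis points from the base point toward the centroid of the selected
#' points (base -> tip).
#'
#' @param cloud a `plant_cloud`.
#' @param leaf_id integer leaf instance id.
#' @param base_point optional precomputed base point (else detected).
#' @return unit numeric length-3 axis.
#' @export
leaf_principal_axis <- function(cloud, leaf_id, base_point = NULL) {
  li <- leaf_point_indices(cloud, leaf_id)
  sel <- li[cloud$semantic[li] == "STEMWORK"]
  if (length(sel) < 3L) sel <- li
  if (length(sel) < 3L) {
    stop("leaf LEAF_", leaf_id, " has fewer than 3 usable points")
  }
  if (is.null(base_point)) base_point <- detect_base_point(cloud, leaf_id)
  pts <- cloud$positions[sel, , drop = FALSE]
  axis <- stats::prcomp(pts, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum(axis * (colMeans(pts) - base_point)) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  names(axis) <- c("x", "y", "z")
  axis
}

#' Phyllotactic orientation of a leaf axis
#'
#' Projects the 3D leaf principal axis onto the horizontal (xoy) plane and
#' renormalizes, giving the compass direction the leaf points in.
#'
#' @param axis unit length-3 leaf axis.
#' @return unit length-2 vector `(x, y)`.
#' @export
phyllotactic_orientation <- function(axis) {
  v <- axis[1:2]
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv <= 1e-9) {
    stop("degenerate projection: leaf axis is vertical")
  }
  out <- v / nv
  names(out) <- c("x", "y")
  out
}

#' Phyllotactic angle between two adjacent leaves
#'
#' Directed angle, counterclockwise viewed from +z, from the lower leaf's
#' phyllotactic orientation to the upper leaf's, in `[0, 360)` degrees. The
#' directed (rather than folded) convention is required for mean angles
#' above 180 degrees to be expressible.
#'
#' @param lower,upper unit length-2 orientation vectors (lower rank first).
#' @return angle in degrees, `[0, 360)`.
#' @export
phyllotactic_angle <- function(lower, upper) {
  a <- atan2(upper[2], upper[1]) - atan2(lower[2], lower[1])
  ((a / DEG2RAD) %% 360 + 360) %% 360
}

#' Rank leaves along the stem
#'
#' Ranks are assigned by ascending base-point z (rank 1 = bottom leaf), ties
#' broken by leaf id.
#'
#' @param base_z named numeric vector of base-point z per leaf, names =
#'   leaf ids.
#' @return named integer vector mapping leaf id -> rank, a permutation of
#'   1..L.
#' @export
assign_leaf_ranks <- function(base_z) {
  ids <- as.integer(names(base_z))
  ord <- order(base_z, ids)
  ranks <- integer(length(base_z))
  ranks[ord] <- seq_along(ord)
  stats::setNames(ranks, names(base_z))
}

#' Compute descriptors for every leaf of a plant
#'
#' Runs base-point detection, principal-axis PCA, horizontal projection and
#' ranking for all leaf instances.
#'
#' @param cloud a `plant_cloud` with leaf instances and a `STEM` instance.
#' @return a `data.frame` with one row per leaf: `leaf_id`, `rank`,
#'   `base_x/y/z`, `axis_x/y/z`, `orient_x/y`, `n_points`, ordered by rank;
#'   attribute `point_indices` holds a list (named by leaf id) of each
#'   leaf's point indices.
#' @export
leaf_descriptors <- function(cloud) {
  ids <- leaf_ids(cloud)
  if (!length(ids)) stop("cloud has no leaf instances")
  rows <- lapply(ids, function(k) {
    bp <- detect_base_point(cloud, k)
    ax <- leaf_principal_axis(cloud, k, base_point = bp)
    ori <- phyllotactic_orientation(ax)
    data.frame(leaf_id = k, base_x = bp[1], base_y = bp[2], base_z = bp[3],
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
               orient_x = ori[1], orient_y = ori[2],
               n_points = length(leaf_point_indices(cloud, k)))
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d$rank <- assign_leaf_ranks(stats::setNames(d$base_z, d$leaf_id))
  d <- d[order(d$rank), c("leaf_id", "rank", setdiff(names(d),
                                                     c("leaf_id", "rank")))]
  rownames(d) <- NULL
  attr(d, "point_indices") <- stats::setNames(
    lapply(d$leaf_id, function(k) leaf_point_indices(cloud, k)),
    d$leaf_id)
  d
}

#' Phyllotactic angles of a plant
#'
#' The adjacent-rank phyllotactic angles (rank 1 to 2, 2 to 3, ...) measured
#' from recovered leaf descriptors.
#'
#' @param cloud a `plant_cloud`, or a precomputed [leaf_descriptors()]
#'   data.frame.
#' @return numeric vector of L-1 angles in degrees, `[0, 360)`.
#' @export
plant_phyllotaxis <- function(cloud) {
  d <- if (is.data.frame(cloud)) cloud else leaf_descriptors(cloud)
  d <- d[order(d$rank), ]
  if (nrow(d) < 2L) return(numeric())
  vapply(seq_len(nrow(d) - 1L), function(i) {
    phyllotactic_angle(c(d$orient_x[i], d$orient_y[i]),
                       c(d$orient_x[i + 1L], d$orient_y[i + 1L]))
  }, numeric(1))
}
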