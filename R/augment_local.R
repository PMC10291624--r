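# Leaf-level augmentations: rigid motions of single leaf instances and the
# within-cultivar leaf crossover. Each is the identity off the moved leaf.

#' Translate every leaf vertically
#'
#' Adds an independent offset `psi_z ~ N(0, sigma_l)` (normalized units) to
#' the z coordinate of each leaf instance, varying the apparent internode
#' lengths. Non-leaf points are untouched; x and y never change. Each
#' leaf's motion is rigid, so the occasional visual detachment of a leaf
#' from the stem at large offsets is an accepted artifact of the method.
#'
#' @param cloud a normalized `plant_cloud` with leaf instances.
#' @param sigma_l offset standard deviation (>= 0), normalized units.
#' @param seed optional integer seed.
#' @param offsets optional named numeric override (names = leaf ids).
#' @return the translated `plant_cloud`.
#' @export
augment_translate_leaves <- function(cloud, sigma_l = 0.7, seed = NULL,
                                     offsets = NULL) {
  require_normalized(cloud)
  ids <- leaf_ids(cloud)
  if (!length(ids)) stop("cloud has no leaf instances")
  if (is.null(offsets)) {
    stopifnot_scalar_number(sigma_l, "sigma_l", lower = 0)
    offsets <- with_seed_maybe(
      seed, stats::setNames(stats::rnorm(length(ids), 0, sigma_l), ids))
  }
  out <- cloud
  for (k in ids) {
    li <- leaf_point_indices(cloud, k)
    out$positions[li, 3] <- out$positions[li, 3] + offsets[[as.character(k)]]
  }
  structure_drawn(out, list(psi_z = offsets))
}

# Shared core: rigid rotation of one leaf's points about a line through
# `pivot` with direction `axis`.
rotate_leaf_points <- function(cloud, leaf_id, axis, angle, pivot) {
  li <- leaf_point_indices(cloud, leaf_id)
  if (!length(li)) stop("leaf LEAF_", leaf_id, " has no points")
  R <- rotation_about_axis(axis, angle)
  out <- cloud
  centered <- sweep(cloud$positions[li, , drop = FALSE], 2L, pivot)
  out$positions[li, ] <- sweep(centered %*% t(R), 2L, pivot, `+`)
  out$normals[li, ] <- cloud$normals[li, , drop = FALSE] %*% t(R)
  out
}

#' Rotate a leaf about the vertical axis
#'
#' Rotates the points of one leaf (or of every leaf when `leaf_id = NULL`)
#' about the vertical line through its base point by `gamma` degrees
#' (`gamma ~ U(-a, a)` when a range half-width is given), changing the
#' leaf's phyllotactic angle. The base point is a fixed point of the
#' motion.
#'
#' @param cloud a normalized `plant_cloud`.
#' @param leaf_id integer leaf id, or `NULL` for all leaves (independent
#'   draws).
#' @param gamma fixed angle in degrees; or `NULL` to draw from
#'   `U(-a, a)`.
#' @param a half-width of the uniform angle range (degrees), used when
#'   `gamma` is `NULL`.
#' @param seed optional integer seed.
#' @param descriptors optional precomputed [leaf_descriptors()].
#' @return the rotated `plant_cloud`.
#' @export
augment_rotate_leaf_z <- function(cloud, leaf_id = NULL, gamma = NULL,
                                  a = 135, seed = NULL, descriptors = NULL) {
  require_normalized(cloud)
  d <- descriptors %||% leaf_descriptors(cloud)
  ids <- if (is.null(leaf_id)) d$leaf_id else leaf_id
  run <- function() {
    out <- cloud
    drawn <- numeric(0)
    for (k in ids) {
      row <- d[d$leaf_id == k, ]
      if (!nrow(row)) stop("no descriptor for leaf LEAF_", k)
      g <- gamma %||% stats::runif(1L, -abs(a), abs(a))
      out <- rotate_leaf_points(out, k, c(0, 0, 1), g,
                                c(row$base_x, row$base_y, row$base_z))
      drawn[as.character(k)] <- g
    }
    structure_drawn(out, list(gamma = drawn))
  }
  with_seed_maybe(seed, run())
}

#' Rotate a leaf about its own principal axis
#'
#' Axis-angle (Rodrigues) rotation of a leaf's points about the line through
#' its base point with the direction of its principal axis, by `theta`
#' degrees (`theta ~ U(-b, b)` when drawn), tilting the leaf blade as a
#' leaf reorients toward light. Points on the axis line are fixed.
#'
#' @param cloud a normalized `plant_cloud`.
#' @param leaf_id integer leaf id, or `NULL` for all leaves.
#' @param theta fixed angle in degrees; or `NULL` to draw from `U(-b, b)`.
#' @param b half-width of the uniform angle range (degrees).
#' @param seed optional integer seed.
#' @param descriptors optional precomputed [leaf_descriptors()].
#' @return the rotated `plant_cloud`.
#' @export
augment_rotate_leaf_pca <- function(cloud, leaf_id = NULL, theta = NULL,
                                    b = 50, seed = NULL, descriptors = NULL) {
  require_normalized(cloud)
  d <- descriptors %||% leaf_descriptors(cloud)
  ids <- if (is.null(leaf_id)) d$leaf_id else leaf_id
  run <- function() {
    out <- cloud
    drawn <- numeric(0)
    for (k in ids) {
      row <- d[d$leaf_id == k, ]
      if (!nrow(row)) stop("no descriptor for leaf LEAF_", k)
      th <- theta %||% stats::runif(1L, -abs(b), abs(b))
      out <- rotate_leaf_points(out, k,
                                c(row$axis_x, row$axis_y, row$axis_z), th,
                                c(row$base_x, row$base_y, row$base_z))
      drawn[as.character(k)] <- th
    }
    structure_drawn(out, list(theta = drawn))
  }
  with_seed_maybe(seed, run())
}

# Uniform random derangement (permutation with no fixed point) of 1..m by
# rejection; m is the number of plants sharing a rank, so small.
random_derangement <- function(m) {
  if (m < 2L) stop("derangement needs at least 2 elements")
  repeat {
    p <- sample.int(m)
    if (all(p != seq_len(m))) return(p)
  }
}

#' Leaf crossover within a cultivar
#'
#' Exchanges same-rank leaves among the plants of one cultivar to diversify
#' plant architectures. For each of `n_c` rounds a morphological rank r
#' (present in at least two plants) is drawn — without repetition across
#' rounds; the rank-r leaf is cut from every plant possessing it, and the
#' cut leaves are reassigned by a uniform random derangement (so no leaf
#' returns to its own plant). Each transplanted leaf is rigidly aligned to
#' the leaf it replaces: rotated about the vertical axis through its base so
#' its phyllotactic orientation matches the replaced leaf's, then translated
#' so the base points coincide. Positions and normals are transformed;
#' colors travel with the leaf; the instance id becomes the replaced leaf's
#' id. Finally every plant is re-down-sampled to `n_target` points.
#'
#' @param clouds list of >= 2 normalized `plant_cloud`s of the same
#'   cultivar.
#' @param n_c number of crossover rounds (leaves exchanged per plant).
#' @param n_target output point count per plant; `NULL` skips the final
#'   re-down-sampling (useful for inspecting the raw graft).
#' @param seed optional integer seed.
#' @return list of augmented `plant_cloud`s (same order); attribute
#'   `swaps` is a data.frame logging rank, donor and receiver of every
#'   transplant, and attribute `n_rounds` the number of rounds actually
#'   performed.
#' @export
augment_crossover <- function(clouds, n_c = 4L, n_target = 50000L,
                              seed = NULL) {
  if (length(clouds) < 2L) stop("crossover needs at least 2 plants")
  stopifnot_scalar_number(n_c, "n_c", lower = 1)
  if (!is.null(n_target)) stopifnot_scalar_number(n_target, "n_target",
                                                  lower = 1)
  cultivars <- vapply(clouds, function(cl) cl$meta$cultivar, "")
  if (length(unique(cultivars)) != 1L) {
    stop("crossover is only defined within one cultivar; got: ",
         paste(unique(cultivars), collapse = ", "))
  }
  lapply(clouds, require_normalized)
  desc <- lapply(clouds, leaf_descriptors)
  run <- function() {
    rank_tab <- table(unlist(lapply(desc, function(d) d$rank)))
    eligible <- as.integer(names(rank_tab)[rank_tab >= 2L])
    if (!length(eligible)) {
      stop("crossover impossible: no rank is shared by 2 or more plants")
    }
    n_rounds <- min(n_c, length(eligible))
    if (n_rounds < n_c) {
      warning(sprintf(
        "only %d of %d requested crossover rounds possible (ranks shared by >= 2 plants)",
        n_rounds, n_c))
    }
    ranks_drawn <- sample(eligible, n_rounds, replace = FALSE)
    out <- clouds
    swaps <- list()
    for (r in ranks_drawn) {
      holders <- which(vapply(desc, function(d) r %in% d$rank, TRUE))
      perm <- random_derangement(length(holders))
      rows <- lapply(holders, function(i) {
        d <- desc[[i]]
        d[d$rank == r, ]
      })
      pieces <- lapply(seq_along(holders), function(h) {
        i <- holders[h]
        cloud_subset(out[[i]],
                     leaf_point_indices(out[[i]], rows[[h]]$leaf_id))
      })
      for (h in seq_along(holders)) {
        i <- holders[h]          # donor plant
        j <- holders[perm[h]]    # receiver plant
        src <- rows[[h]]         # donor leaf descriptor
        dst <- rows[[which(holders == j)]]  # leaf being replaced
        piece <- pieces[[h]]
        dgamma <- phyllotactic_angle(c(src$orient_x, src$orient_y),
                                     c(dst$orient_x, dst$orient_y))
        R <- rot_z(dgamma)
        src_base <- c(src$base_x, src$base_y, src$base_z)
        dst_base <- c(dst$base_x, dst$base_y, dst$base_z)
        pos <- sweep(piece$positions, 2L, src_base)
        pos <- sweep(pos %*% t(R), 2L, dst_base, `+`)
        piece$positions <- pos
        piece$normals <- piece$normals %*% t(R)
        piece$instance <- rep(paste0("LEAF_", dst$leaf_id), n_points(piece))
        # remove the receiver's own rank-r leaf, then graft the transplant
        keep <- out[[j]]$instance != paste0("LEAF_", dst$leaf_id)
        host <- cloud_subset(out[[j]], which(keep))
        out[[j]] <- plant_cloud(
          rbind(host$positions, piece$positions),
          rbind(host$normals, piece$normals),
          rbind(host$colors, piece$colors),
          c(as.character(host$semantic), as.character(piece$semantic)),
          c(host$instance, piece$instance),
          out[[j]]$meta, validate = FALSE)
        swaps[[length(swaps) + 1L]] <- data.frame(
          rank = r, donor = i, receiver = j,
          donor_leaf = src$leaf_id, receiver_leaf = dst$leaf_id)
      }
    }
    if (!is.null(n_target)) {
      out <- lapply(out, downsample_cloud, n_target = n_target,
                    mode = "online")
    }
    attr(out, "swaps") <- do.call(rbind, swaps)
    attr(out, "n_rounds") <- n_rounds
    out
  }
  with_seed_maybe(seed, run())
}
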