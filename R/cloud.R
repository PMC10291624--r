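#' Semantic class levels
#'
#' Per-point semantic classes of the plant-part segmentation task: soil base,
#' support stick, stemwork (main stem, petioles, rachis, petiolules), other
#' bio-structures (leaflets, fruits, ...), and unclassified points that could
#' not be labeled.
#'
#' @export
SEMANTIC_CLASSES <- c("SOIL_BASE", "STICK", "STEMWORK", "OTHER_BIO",
                      "UNCLASSIFIED")

#' Semantic classes that take part in evaluation (UNCLASSIFIED excluded)
#' @export
EVAL_CLASSES <- c("SOIL_BASE", "STICK", "STEMWORK", "OTHER_BIO")

#' Number of cameras contributing RGB channels
#' @export
N_CAMERAS <- 15L

color_channel_names <- function() {
  cam <- sprintf("%02d", seq_len(N_CAMERAS))
  as.vector(rbind(paste0("r", cam), paste0("g", cam), paste0("b", cam)))
}

#' Construct a labeled plant point cloud
#'
#' The central container of the package: per-point 3D positions, unit surface
#' normals, RGB color from each of 15 cameras (camera-major, 45 channels),
#' a semantic label and an instance label, plus normalization metadata.
#'
#' Positions are in millimetres for a raw cloud; after [normalize_cloud()]
#' they are in height-normalized units (plant height = 1).
#'
#' @param positions n x 3 numeric matrix (columns x, y, z).
#' @param normals n x 3 numeric matrix of unit vectors.
#' @param colors n x 45 numeric matrix in `[0, 1]` (camera-major r, g, b
#'   triplets: r01, g01, b01, ..., r15, g15, b15). Values above 1 are allowed
#'   after a brightness augmentation.
#' @param semantic character or factor of per-point semantic classes, one of
#'   `SOIL_BASE, STICK, STEMWORK, OTHER_BIO, UNCLASSIFIED`.
#' @param instance character vector of per-point instance labels:
#'   `SOIL_BASE`, `STICK`, `STEM` (main stem only), `LEAF_k` (k >= 1), or
#'   `UNCLASSIFIED`.
#' @param meta list of metadata: `plant_id`, `cultivar`, `normalized` flag,
#'   and (once normalized) `height_scale` (mm), `xy_offset` (mm, length 2),
#'   `z_offset` (mm).
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `plant_cloud`.
#' @export
plant_cloud <- function(positions, normals, colors, semantic, instance,
                        meta = list(), validate = TRUE) {
  positions <- as.matrix(positions)
  normals <- as.matrix(normals)
  colors <- as.matrix(colors)
  colnames(positions) <- c("x", "y", "z")
  colnames(normals) <- c("nx", "ny", "nz")
  colnames(colors) <- color_channel_names()
  semantic <- factor(as.character(semantic), levels = SEMANTIC_CLASSES)
  instance <- as.character(instance)
  defaults <- list(plant_id = "plant", cultivar = "unknown",
                   normalized = FALSE, height_scale = NA_real_,
                   xy_offset = c(NA_real_, NA_real_), z_offset = NA_real_)
  meta <- utils::modifyList(defaults, meta)
  x <- structure(list(positions = positions, normals = normals,
                      colors = colors, semantic = semantic,
                      instance = instance, meta = meta),
                 class = "plant_cloud")
  if (validate) validate_cloud(x)
  x
}

#' Validate a plant_cloud object
#'
#' Checks the structural invariants: consistent lengths, finite positions,
#' unit normals (1e-6), non-negative colors, known label vocabulary, and
#' contiguous leaf instance ids 1..L. For a cloud flagged as normalized and
#' not yet augmented the geometric invariants min(z)=0, max(z)=1 and
#' centered x, y are checked by [normalize_cloud()] itself, not here, since
#' augmentations intentionally break them.
#'
#' @param x a `plant_cloud`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_cloud <- function(x) {
  stopifnot(inherits(x, "plant_cloud"))
  n <- nrow(x$positions)
  if (n < 1L) stop("plant_cloud must contain at least one point")
  if (ncol(x$positions) != 3L) stop("positions must be n x 3")
  if (!all(dim(x$normals) == c(n, 3L))) stop("normals must be n x 3")
  if (!all(dim(x$colors) == c(n, 3L * N_CAMERAS))) {
    stop("colors must be n x 45 (15 cameras x RGB)")
  }
  if (length(x$semantic) != n || length(x$instance) != n) {
    stop("labels must have one entry per point")
  }
  if (anyNA(x$positions) || any(!is.finite(x$positions))) {
    stop("positions contain NaN or non-finite values")
  }
  nn <- sqrt(rowSums(x$normals^2))
  if (any(abs(nn - 1) > 1e-6)) {
    stop("normals must be unit vectors (|norm - 1| <= 1e-6)")
  }
  if (any(x$colors < 0)) stop("colors must be >= 0")
  if (anyNA(x$semantic)) stop("unknown semantic class code")
  ok <- x$instance %in% c("SOIL_BASE", "STICK", "STEM", "UNCLASSIFIED") |
    grepl("^LEAF_[0-9]+$", x$instance)
  if (!all(ok)) {
    stop("unknown instance label: ", x$instance[which(!ok)[1]])
  }
  ids <- leaf_ids(x)
  if (length(ids) && !identical(ids, seq_along(ids))) {
    stop("leaf instance ids must form a contiguous set 1..L")
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param x a `plant_cloud`.
#' @return integer point count.
#' @export
n_points <- function(x) nrow(x$positions)

#' Leaf instance ids present in a cloud
#' @param x a `plant_cloud`.
#' @return sorted integer vector of k for which `LEAF_k` occurs.
#' @export
leaf_ids <- function(x) {
  lv <- unique(x$instance)
  lv <- lv[grepl("^LEAF_[0-9]+$", lv)]
  sort(as.integer(sub("^LEAF_", "", lv)))
}

#' Subset a cloud by point index
#'
#' All per-point attributes are subset consistently; metadata is carried over.
#' Indices may repeat (sampling with replacement).
#'
#' @param x a `plant_cloud`.
#' @param idx integer indices into the points.
#' @return a `plant_cloud` with `length(idx)` points.
#' @export
cloud_subset <- function(x, idx) {
  plant_cloud(x$positions[idx, , drop = FALSE],
              x$normals[idx, , drop = FALSE],
              x$colors[idx, , drop = FALSE],
              x$semantic[idx], x$instance[idx], x$meta, validate = FALSE)
}

#' @export
print.plant_cloud <- function(x, ...) {
  cat(sprintf("<plant_cloud> %s (%s), %d points, %s\n",
              x$meta$plant_id, x$meta$cultivar, n_points(x),
              if (isTRUE(x$meta$normalized)) "normalized" else "raw (mm)"))
  tab <- table(x$semantic)
  cat("  semantic:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  leaves: %d\n", length(leaf_ids(x))))
  invisible(x)
}

#' @export
summary.plant_cloud <- function(object, ...) {
  print(object)
  rng <- apply(object$positions, 2, range)
  cat(sprintf("  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3],
              rng[2, 3]))
  invisible(object)
}
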