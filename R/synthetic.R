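# Procedural generator of labeled tomato-like point clouds with known
# ground truth. It emulates the structure of greenhouse scans: a soil disk,
# a vertical main stem with a parallel support stick, and 6-9 compound
# leaves attached at ranked heights whose azimuths follow the measured
# phyllotaxis distribution N(185.1 deg, 57.0 deg).

#' Configuration for the synthetic plant generator
#'
#' Defaults reflect measured greenhouse tomato statistics: 6-9 leaves with
#' mean 7.4 per plant, adjacent-leaf phyllotactic angles `N(185.1, 57.0)`
#' degrees, stem heights 500-700 mm. All lengths are millimetres.
#'
#' @param leaf_count_pmf probabilities of 6, 7, 8, 9 leaves (sums to 1;
#'   default `c(0.2, 0.3, 0.4, 0.1)`, mean 7.4).
#' @param phyllotaxis_mean,phyllotaxis_sd mean and sd (degrees) of the
#'   Gaussian adjacent-leaf azimuth increment.
#' @param stem_height_range `(min, max)` mm of the uniform stem height.
#' @param stem_radius,stick_radius cylinder radii, mm.
#' @param stick_offset distance of the support stick from the stem axis, mm.
#' @param petiole_length mean petiole+rachis length, mm.
#' @param leaflet_count leaflets per leaf.
#' @param soil_radius soil disk radius, mm.
#' @param points_per_plant total points emitted per plant (scalable; raw
#'   greenhouse scans run to ~4e5 points, desk-scale tests use far fewer).
#' @param position_noise_sd isotropic Gaussian surface noise, mm.
#' @param camera_brightness_jitter_sd sd of the per-camera brightness
#'   factor `1 + N(0, sd)`.
#' @param leaf_elevation_mean,leaf_elevation_sd petiole elevation above the
#'   horizontal, degrees.
#' @return a `synthetic_plant_config` list.
#' @export
synthetic_plant_config <- function(leaf_count_pmf = c(0.2, 0.3, 0.4, 0.1),
                                   phyllotaxis_mean = 185.1,
                                   phyllotaxis_sd = 57.0,
                                   stem_height_range = c(500, 700),
                                   stem_radius = 5,
                                   stick_radius = 4,
                                   stick_offset = 40,
                                   petiole_length = 130,
                                   leaflet_count = 5L,
                                   soil_radius = 75,
                                   points_per_plant = 100000L,
                                   position_noise_sd = 0.6,
                                   camera_brightness_jitter_sd = 0.08,
                                   leaf_elevation_mean = 25,
                                   leaf_elevation_sd = 12) {
  if (length(leaf_count_pmf) != 4L || any(leaf_count_pmf < 0) ||
      abs(sum(leaf_count_pmf) - 1) > 1e-9) {
    stop("leaf_count_pmf must be 4 non-negative probabilities summing to 1")
  }
  stopifnot_scalar_number(phyllotaxis_sd, "phyllotaxis_sd", lower = 0)
  stopifnot_scalar_number(points_per_plant, "points_per_plant", lower = 50)
  check_range(stem_height_range, "stem_height_range", positive = TRUE)
  structure(as.list(environment()), class = "synthetic_plant_config")
}

# ---- geometric primitives: each returns positions + analytic normals ----

sample_disk <- function(n, radius, z) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(p = cbind(r * cos(th), r * sin(th), rep(z, n)),
       n = cbind(0, 0, rep(1, n)))
}

sample_cylinder <- function(n, center_xy, radius, z0, z1) {
  th <- stats::runif(n, 0, 2 * pi)
  z <- stats::runif(n, z0, z1)
  list(p = cbind(center_xy[1] + radius * cos(th),
                 center_xy[2] + radius * sin(th), z),
       n = cbind(cos(th), sin(th), 0))
}

# Tube from `base` along unit direction `dir`, length L, radius rho.
sample_tube <- function(n, base, dir, len, rho) {
  dir <- dir / sqrt(sum(dir^2))
  u <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(dir[2] * u[3] - dir[3] * u[2],
          dir[3] * u[1] - dir[1] * u[3],
          dir[1] * u[2] - dir[2] * u[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  t <- stats::runif(n, 0, len)
  th <- stats::runif(n, 0, 2 * pi)
  ct <- cos(th); st <- sin(th)
  p <- outer(rep(1, n), base) + outer(t, dir) +
    rho * (outer(ct, e1) + outer(st, e2))
  nrm <- outer(ct, e1) + outer(st, e2)
  list(p = p, n = nrm)
}

# Planar elliptical leaflet patch centered at `center`, long semi-axis a
# along `dir`, short semi-axis b, plane normal `nrm`.
sample_leaflet <- function(n, center, dir, nrm, a, b) {
  dir <- dir / sqrt(sum(dir^2))
  nrm <- nrm / sqrt(sum(nrm^2))
  e2 <- c(nrm[2] * dir[3] - nrm[3] * dir[2],
          nrm[3] * dir[1] - nrm[1] * dir[3],
          nrm[1] * dir[2] - nrm[2] * dir[1])
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  p <- outer(rep(1, n), center) + outer(a * r * cos(th), dir) +
    outer(b * r * sin(th), e2)
  list(p = p, n = outer(rep(1, n), nrm))
}

# Per-class base RGB used for the 15-camera color channels.
class_palette <- function() {
  rbind(SOIL_BASE = c(0.35, 0.23, 0.12),
        STICK = c(0.65, 0.62, 0.55),
        STEMWORK = c(0.30, 0.55, 0.20),
        OTHER_BIO = c(0.18, 0.45, 0.12))
}

make_colors <- function(semantic, jitter_sd) {
  pal <- class_palette()
  fac <- 1 + stats::rnorm(N_CAMERAS, 0, jitter_sd)
  base <- pal[semantic, , drop = FALSE]
  cols <- do.call(cbind, lapply(seq_len(N_CAMERAS), function(c) base * fac[c]))
  pmin(pmax(cols, 0), 1)
}

#' Generate one synthetic labeled plant
#'
#' Emits a labeled raw (mm) point cloud — soil disk, support stick, main
#' stem, and L leaves each consisting of a petiole/rachis tube (semantic
#' `STEMWORK`, instance `LEAF_k`) carrying elliptical leaflet patches
#' (`OTHER_BIO`, `LEAF_k`) — together with the ground truth needed to
#' validate the geometry-recovery pipeline.
#'
#' Leaf k+1's azimuth is leaf k's azimuth plus a draw from
#' `N(phyllotaxis_mean, phyllotaxis_sd)` (mod 360). Surface normals are
#' analytic; colors are a per-class base RGB modulated per camera by
#' `1 + N(0, jitter_sd)` and clipped to `[0, 1]`.
#'
#' @param config a [synthetic_plant_config()].
#' @param seed optional integer seed (plant is deterministic given it).
#' @param plant_id,cultivar metadata strings.
#' @return a list with elements `cloud` (raw `plant_cloud`) and `truth`
#'   (list: `n_leaves`, `base_points` L x 3, `axes` L x 3 unit rows,
#'   `ranks`, `azimuths_deg`, `phyllotaxis_deg` (L-1 adjacent angles),
#'   `attach_z`, `stem_height`).
#' @export
generate_plant <- function(config = synthetic_plant_config(), seed = NULL,
                           plant_id = "synthetic", cultivar = "Merlice") {
  stopifnot(inherits(config, "synthetic_plant_config"))
  with_seed_maybe(seed, generate_plant_impl(config, plant_id, cultivar))
}

generate_plant_impl <- function(cfg, plant_id, cultivar) {
  h <- stats::runif(1L, cfg$stem_height_range[1], cfg$stem_height_range[2])
  L <- sample(6:9, 1L, prob = cfg$leaf_count_pmf)
  # ranked attachment heights: ordered, spread over the stem with jitter
  frac <- (seq_len(L) - 0.5) / L
  attach_z <- sort(0.15 * h + (0.92 - 0.15) * h * frac +
                     stats::rnorm(L, 0, 0.02 * h))
  attach_z <- pmin(pmax(attach_z, 0.05 * h), 0.98 * h)
  az <- numeric(L)
  az[1] <- stats::runif(1L, 0, 360)
  incr <- if (L > 1L) stats::rnorm(L - 1L, cfg$phyllotaxis_mean,
                                   cfg$phyllotaxis_sd) else numeric()
  for (k in seq_len(L - 1L)) az[k + 1L] <- az[k] + incr[k]
  elev <- stats::rnorm(L, cfg$leaf_elevation_mean, cfg$leaf_elevation_sd)
  pet_len <- cfg$petiole_length * stats::runif(L, 0.85, 1.15)

  # point budget: fixed organ shares, remainder split evenly over leaves
  n <- as.integer(cfg$points_per_plant)
  n_soil <- max(20L, as.integer(0.15 * n))
  n_stick <- max(10L, as.integer(0.05 * n))
  n_stem <- max(30L, as.integer(0.12 * n))
  n_leaf <- max(30L, as.integer((n - n_soil - n_stick - n_stem) / L))

  parts <- list()
  add <- function(geom, semantic, instance) {
    parts[[length(parts) + 1L]] <<- list(
      p = geom$p, n = geom$n,
      sem = rep(semantic, nrow(geom$p)), inst = rep(instance, nrow(geom$p)))
  }
  add(sample_disk(n_soil, cfg$soil_radius, 0), "SOIL_BASE", "SOIL_BASE")
  add(sample_cylinder(n_stick, c(cfg$stick_offset, 0), cfg$stick_radius,
                      0, h), "STICK", "STICK")
  add(sample_cylinder(n_stem, c(0, 0), cfg$stem_radius, 0, h),
      "STEMWORK", "STEM")

  truth_axes <- matrix(0, L, 3)
  truth_base <- matrix(0, L, 3)
  for (k in seq_len(L)) {
    a <- az[k] * DEG2RAD
    e <- elev[k] * DEG2RAD
    dir <- c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
    base <- c(cfg$stem_radius * cos(a), cfg$stem_radius * sin(a),
              attach_z[k])
    truth_axes[k, ] <- dir
    truth_base[k, ] <- base
    inst <- paste0("LEAF_", k)
    n_pet <- max(12L, as.integer(0.35 * n_leaf))
    n_blade <- max(10L, n_leaf - n_pet)
    add(sample_tube(n_pet, base, dir, pet_len[k], 2), "STEMWORK", inst)
    # leaflets along the distal 60% of the rachis
    n_ll <- max(1L, as.integer(cfg$leaflet_count))
    per <- max(4L, as.integer(n_blade / n_ll))
    side <- c(0, 0, 1)  # blade roughly horizontal, normal tilted with dir
    blade_n <- side - sum(side * dir) * dir
    blade_n <- blade_n / sqrt(sum(blade_n^2))
    for (m in seq_len(n_ll)) {
      t_frac <- 0.4 + 0.6 * (m - 0.5) / n_ll
      center <- base + t_frac * pet_len[k] * dir +
        c(0, 0, 2 + stats::rnorm(1, 0, 1))
      add(sample_leaflet(per, center, dir, blade_n,
                         a = 0.22 * pet_len[k], b = 0.12 * pet_len[k]),
          "OTHER_BIO", inst)
    }
  }

  p <- do.call(rbind, lapply(parts, `[[`, "p"))
  nrm <- do.call(rbind, lapply(parts, `[[`, "n"))
  sem <- unlist(lapply(parts, `[[`, "sem"))
  inst <- unlist(lapply(parts, `[[`, "inst"))
  if (cfg$position_noise_sd > 0) {
    p <- p + matrix(stats::rnorm(length(p), 0, cfg$position_noise_sd),
                    nrow(p), 3)
  }
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cols <- make_colors(sem, cfg$camera_brightness_jitter_sd)
  cloud <- plant_cloud(p, nrm, cols, sem, inst,
                       meta = list(plant_id = plant_id, cultivar = cultivar))
  phyllo <- if (L > 1L) ((incr %% 360) + 360) %% 360 else numeric()
  truth <- list(n_leaves = L, base_points = truth_base, axes = truth_axes,
                ranks = seq_len(L), azimuths_deg = az %% 360,
                phyllotaxis_deg = phyllo, attach_z = attach_z,
                stem_height = h)
  list(cloud = cloud, truth = truth)
}

#' Generate a dataset of synthetic plants
#'
#' Generates `n_plants` plants, cycling cultivar tags, optionally writing
#' each cloud to `out_dir` plus a `manifest.tsv` (file, plant_id, cultivar,
#' seed, points, leaves). Plant i is deterministic given `(seed, i)`.
#'
#' @param config a [synthetic_plant_config()].
#' @param n_plants number of plants (>= 1).
#' @param cultivars character vector of cultivar names to cycle.
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @param seed integer base seed.
#' @param format file format for written clouds (see [write_cloud()]).
#' @return invisibly, a list with `plants` (list of `generate_plant()`
#'   results) and `manifest` (data.frame).
#' @export
generate_dataset <- function(config = synthetic_plant_config(), n_plants,
                             cultivars = c("Merlice", "Brioso",
                                           "GardenersDelight"),
                             out_dir = NULL, seed = 1L, format = "ply") {
  stopifnot_scalar_number(n_plants, "n_plants", lower = 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", n_plants)
  plants <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    cv <- cultivars[((i - 1L) %% length(cultivars)) + 1L]
    id <- sprintf("plant_%04d", i)
    s <- child_seed(seed, i)
    plants[[i]] <- generate_plant(config, seed = s, plant_id = id,
                                  cultivar = cv)
    fname <- paste0(id, if (format == "tsv") ".tsv" else ".ply")
    if (!is.null(out_dir)) {
      write_cloud(plants[[i]]$cloud, file.path(out_dir, fname),
                  format = format)
    }
    rows[[i]] <- data.frame(file = fname, plant_id = id, cultivar = cv,
                            seed = s,
                            points = n_points(plants[[i]]$cloud),
                            leaves = plants[[i]]$truth$n_leaves)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t")
  }
  invisible(list(plants = plants, manifest = manifest))
}
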