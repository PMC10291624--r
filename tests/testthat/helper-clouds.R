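# Fixtures built in code: tiny hand-made clouds and desk-scale synthetic
# plants shared across test files.

# A minimal raw cloud with explicit values: 2 soil points, 3 stem points,
# and a 4-point leaf whose petiole is collinear.
tiny_cloud <- function() {
  pos <- rbind(c(-10, 0, 0), c(10, 5, 0),            # soil
               c(0, 0, 100), c(0, 0, 400), c(0, 0, 700),  # stem
               c(5, 0, 400), c(55, 0, 410), c(105, 0, 420),  # petiole
               c(155, 0, 430))                        # leaflet tip
  nrm <- matrix(rep(c(0, 0, 1), 9), ncol = 3, byrow = TRUE)
  cols <- matrix(0.5, 9, 45)
  sem <- c("SOIL_BASE", "SOIL_BASE", "STEMWORK", "STEMWORK", "STEMWORK",
           "STEMWORK", "STEMWORK", "STEMWORK", "OTHER_BIO")
  inst <- c("SOIL_BASE", "SOIL_BASE", "STEM", "STEM", "STEM",
            "LEAF_1", "LEAF_1", "LEAF_1", "LEAF_1")
  plant_cloud(pos, nrm, cols, sem, inst,
              meta = list(plant_id = "tiny", cultivar = "TestCv"))
}

# Cached normalized synthetic plants (moderate density) for reuse.
test_plant <- local({
  cache <- list()
  function(seed = 11, points = 4000) {
    key <- paste(seed, points)
    if (is.null(cache[[key]])) {
      g <- generate_plant(synthetic_plant_config(points_per_plant = points),
                          seed = seed)
      cache[[key]] <<- list(cloud = normalize_cloud(g$cloud),
                            raw = g$cloud, truth = g$truth)
    }
    cache[[key]]
  }
})

expect_cloud_equal <- function(a, b, pos_tol = 1e-6) {
  expect_equal(dim(a$positions), dim(b$positions))
  expect_lt(max(abs(a$positions - b$positions)), pos_tol)
  expect_lt(max(abs(a$normals - b$normals)), 1e-6)
  expect_lt(max(abs(a$colors - b$colors)), 1e-9)
  expect_identical(as.character(a$semantic), as.character(b$semantic))
  expect_identical(a$instance, b$instance)
}

# max |pairwise distance change| over sampled point pairs
max_pairdist_change <- function(p_before, p_after, n_pairs = 1000,
                                seed = 99) {
  withr::with_seed(seed, {
    n <- nrow(p_before)
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    d0 <- sqrt(rowSums((p_before[i, ] - p_before[j, ])^2))
    d1 <- sqrt(rowSums((p_after[i, ] - p_after[j, ])^2))
    max(abs(d1 - d0))
  })
}

angle_between_deg <- function(u, v) {
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# exact median nearest-neighbour spacing of a cloud (clouds used in tests
# are small enough for the full distance matrix)
median_nn_spacing <- function(cloud) {
  d <- as.matrix(stats::dist(cloud$positions))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}
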