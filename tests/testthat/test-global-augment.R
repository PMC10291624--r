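# The seven whole-cloud augmentations.

test_that("every global transform at identity parameters is the identity", {
  cl <- test_plant()$cloud
  checks <- list(
    augment_jitter(cl, sigma = 0, seed = 1),
    augment_scale_xy(cl, range = c(1, 1), seed = 1),
    augment_rotate_global(cl, angles = c(0, 0, 0)),
    augment_translate_global(cl, range = c(0, 0), seed = 1),
    augment_brightness(cl, range = c(1, 1), seed = 1))
  for (out in checks) {
    expect_lt(max(abs(out$positions - cl$positions)), 1e-12)
    expect_lt(max(abs(out$colors - cl$colors)), 1e-12)
  }
  # phi = 0 keeps all points before re-sampling
  kept <- augment_crop(cl, phi = 0, n_target = n_points(cl), seed = 1)
  expect_equal(sort(kept$positions[, 3]), sort(cl$positions[, 3]))
})

test_that("jitter displacement moments match N(0, sigma)", {
  cl <- downsample_cloud(test_plant()$cloud, 4000, "offline", seed = 1)
  sigma <- 0.08
  out <- augment_jitter(cl, sigma, seed = 42)
  disp <- out$positions - cl$positions
  n <- length(disp) / 3
  for (ax in 1:3) {
    expect_lt(abs(sd(disp[, ax]) - sigma), 3 * sigma / sqrt(2 * n))
    expect_lt(abs(mean(disp[, ax])), 3 * sigma / sqrt(n))
  }
  # labels, normals, colors untouched
  expect_identical(out$instance, cl$instance)
  expect_identical(out$normals, cl$normals)
  expect_identical(out$colors, cl$colors)
  expect_error(augment_jitter(cl, -0.1), ">=")
})

test_that("scaling multiplies x and y only, with uniform factors", {
  cl <- test_plant()$cloud
  out <- augment_scale_xy(cl, eta = c(1, 0.75))
  i <- which.max(abs(cl$positions[, 2]))
  expect_equal(unname(out$positions[i, 2]),
               unname(0.75 * cl$positions[i, 2]))
  expect_identical(out$positions[, 3], cl$positions[, 3])
  expect_identical(out$positions[, 1], cl$positions[, 1])
  # the worked single-point case: (0.2, 0.4, 0.9) with eta_y = 0.75
  pt <- plant_cloud(rbind(c(0.2, 0.4, 0.9), c(0, 0, 0)),
                    rbind(c(0, 0, 1), c(0, 0, 1)), matrix(0, 2, 45),
                    rep("STEMWORK", 2), rep("STEM", 2),
                    meta = list(normalized = TRUE))
  expect_equal(unname(augment_scale_xy(pt, eta = c(1, 0.75))$positions[1, ]),
               c(0.2, 0.3, 0.9), tolerance = 1e-15)
  # drawn factors are U(a, b): KS test over many seeded draws
  etas <- sapply(1:2000, function(s)
    attr(augment_scale_xy(pt, range = c(0.5, 1.5), seed = s),
         "drawn")$eta_x)
  expect_gt(stats::ks.test(etas, "punif", 0.5, 1.5)$p.value, 0.01)
  expect_error(augment_scale_xy(cl, range = c(0, 1)), "> 0")
})

test_that("global rotation is an isometry that carries the normals", {
  cl <- test_plant()$cloud
  # canonical 90 degree z-rotation
  pt <- plant_cloud(rbind(c(0.1, 0, 0.5), c(0, 0, 0)),
                    rbind(c(1, 0, 0), c(0, 0, 1)), matrix(0, 2, 45),
                    rep("STEMWORK", 2), rep("STEM", 2),
                    meta = list(normalized = TRUE))
  out <- augment_rotate_global(pt, angles = c(0, 0, 90))
  expect_equal(unname(out$positions[1, ]), c(0, 0.1, 0.5),
               tolerance = 1e-12)
  expect_equal(unname(out$normals[1, ]), c(0, 1, 0), tolerance = 1e-12)
  # any sampled rotation preserves pairwise distances to 1e-9
  rot <- augment_rotate_global(cl, sigma_r = 3, seed = 5)
  expect_lt(max_pairdist_change(cl$positions, rot$positions), 1e-9)
  # rotated normals stay unit
  expect_lt(max(abs(sqrt(rowSums(rot$normals^2)) - 1)), 1e-9)
  expect_identical(as.character(rot$semantic), as.character(cl$semantic))
})

test_that("global translation shifts all points by one drawn offset", {
  cl <- test_plant()$cloud
  out <- augment_translate_global(cl, delta = c(0.02, 0.05, 0.005))
  expect_equal(unname(out$positions[1, ] - cl$positions[1, ]),
               c(0.02, 0.05, 0.005), tolerance = 1e-15)
  # pairwise difference vectors unchanged (to floating-point rounding)
  d0 <- cl$positions[2:10, ] - cl$positions[1:9, ]
  d1 <- out$positions[2:10, ] - out$positions[1:9, ]
  expect_lt(max(abs(d1 - d0)), 1e-12)
  rnd <- augment_translate_global(cl, range = c(-0.05, 0.05), seed = 9)
  drawn <- attr(rnd, "drawn")
  expect_true(all(abs(unlist(drawn)) <= 0.05))
})

test_that("cropping applies the closed-interval box rule then resamples", {
  # hand-derived toy case: with phi = 0.25 exactly one point survives
  toy_pos <- rbind(c(-0.4, -0.4, 0.0), c(0.4, 0.4, 0.1), c(0, 0, 0.5),
                   c(-0.2, 0.3, 0.9), c(0.1, -0.1, 1.0))
  toy <- plant_cloud(toy_pos, matrix(rep(c(0, 0, 1), 5), ncol = 3,
                                     byrow = TRUE),
                     matrix(0.1, 5, 45), rep("STEMWORK", 5),
                     rep("STEM", 5), meta = list(normalized = TRUE))
  out <- augment_crop(toy, phi = 0.25, n_target = 1, seed = 1)
  expect_equal(unname(out$positions[1, ]), c(0, 0, 0.5))
  # drawn phi with fixed-size contract
  cl <- test_plant()$cloud
  for (s in 1:5) {
    out <- augment_crop(cl, range = c(0, 0.15), n_target = 1234, seed = s)
    expect_identical(n_points(out), 1234L)
  }
  # an impossible crop errors instead of returning an empty cloud
  expect_error(augment_crop(toy, phi = 0.999, n_target = 1, seed = 1),
               "empty crop")
})

test_that("brightness scales all 45 channels by one common factor", {
  cl <- test_plant()$cloud
  cl$colors[1, 1] <- 0.30
  out <- augment_brightness(cl, eta = 2.0)
  expect_equal(out$colors, cl$colors * 2.0, tolerance = 1e-15)
  # a channel at 0.30 becomes 0.60
  expect_equal(out$colors[1, 1], 0.60, tolerance = 1e-12)
  # drawn factor: output/input ratio constant across channels to 1e-12
  rnd <- augment_brightness(cl, range = c(0.5, 3.0), seed = 4)
  ratio <- rnd$colors[cl$colors > 0] / cl$colors[cl$colors > 0]
  expect_lt(diff(range(ratio)), 1e-12)
  # positions and labels untouched; colors may exceed 1 (no clipping)
  expect_identical(rnd$positions, cl$positions)
  expect_identical(rnd$instance, cl$instance)
  big <- augment_brightness(cl, eta = 3.0)
  expect_gt(max(big$colors), 1)
})

test_that("no global method except crop changes the point count or labels", {
  cl <- downsample_cloud(test_plant()$cloud, 1500, "offline", seed = 2)
  outs <- list(augment_jitter(cl, 0.08, seed = 1),
               augment_scale_xy(cl, seed = 1),
               augment_rotate_global(cl, seed = 1),
               augment_translate_global(cl, seed = 1),
               augment_brightness(cl, seed = 1))
  for (out in outs) {
    expect_identical(n_points(out), n_points(cl))
    expect_identical(as.character(out$semantic), as.character(cl$semantic))
    expect_identical(out$instance, cl$instance)
  }
})
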