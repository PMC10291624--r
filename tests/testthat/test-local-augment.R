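# Leaf-level augmentations: rigid on the leaf, identity elsewhere.

test_that("leaf translation moves exactly the targeted leaf, in z only", {
  plant <- test_plant()
  cl <- plant$cloud
  ids <- leaf_ids(cl)
  offs <- stats::setNames(rep(0, length(ids)), ids)
  offs["1"] <- 0.1
  out <- augment_translate_leaves(cl, offsets = offs)
  li <- which(cl$instance == "LEAF_1")
  other <- setdiff(seq_len(n_points(cl)), li)
  expect_equal(out$positions[li, 3], cl$positions[li, 3] + 0.1,
               tolerance = 1e-15)
  expect_identical(out$positions[other, ], cl$positions[other, ])
  # x, y unchanged bit-for-bit everywhere
  expect_identical(out$positions[, 1:2], cl$positions[, 1:2])
  # rigid within the leaf
  expect_lt(max_pairdist_change(cl$positions[li, ], out$positions[li, ]),
            1e-12)
  # 0.1 of a 657mm-high plant is 65.7mm raw: the offset is height-relative
  h <- cl$meta$height_scale
  raw0 <- denormalize_cloud(cl)
  raw1 <- denormalize_cloud(out)
  expect_equal(unname(raw1$positions[li[1], 3] - raw0$positions[li[1], 3]),
               0.1 * h, tolerance = 1e-9)
  # sigma 0 is the identity; negative sigma errors
  idt <- augment_translate_leaves(cl, sigma_l = 0, seed = 1)
  expect_identical(idt$positions, cl$positions)
  expect_error(augment_translate_leaves(cl, sigma_l = -1), ">=")
})

test_that("leaf z-rotation pivots on the base point and shifts the
           phyllotactic orientation by gamma", {
  plant <- test_plant()
  cl <- plant$cloud
  d <- leaf_descriptors(cl)
  out <- augment_rotate_leaf_z(cl, leaf_id = 2, gamma = 60,
                               descriptors = d)
  li <- which(cl$instance == "LEAF_2")
  other <- setdiff(seq_len(n_points(cl)), li)
  expect_identical(out$positions[other, ], cl$positions[other, ])
  # base point is a fixed point
  bi <- attr(detect_base_point(cl, 2), "point_index")
  expect_lt(max(abs(out$positions[bi, ] - cl$positions[bi, ])), 1e-9)
  # recomputed orientation moved by 60 degrees (mod 360)
  d1 <- leaf_descriptors(out)
  ang <- phyllotactic_angle(
    c(d$orient_x[d$leaf_id == 2], d$orient_y[d$leaf_id == 2]),
    c(d1$orient_x[d1$leaf_id == 2], d1$orient_y[d1$leaf_id == 2]))
  expect_lt(min(abs(ang - 60), 360 - abs(ang - 60)), 1)
  # rigid within the leaf
  expect_lt(max_pairdist_change(cl$positions[li, ], out$positions[li, ]),
            1e-9)
  # full turn and gamma / -gamma compositions are identities
  full <- augment_rotate_leaf_z(cl, leaf_id = 2, gamma = 360,
                                descriptors = d)
  expect_lt(max(abs(full$positions - cl$positions)), 1e-9)
  fwd <- augment_rotate_leaf_z(cl, leaf_id = 2, gamma = 47,
                               descriptors = d)
  back <- augment_rotate_leaf_z(fwd, leaf_id = 2, gamma = -47,
                                descriptors = d)
  expect_lt(max(abs(back$positions - cl$positions)), 1e-9)
})

test_that("principal-axis rotation matches the closed-form Rodrigues case", {
  R <- rotation_about_axis(c(0, 0, 1), 60)
  expect_equal(as.numeric(R %*% c(0.1, 0, 0)), c(0.05, 0.0866025403784,
                                                 0), tolerance = 1e-10)
  expect_error(rotation_about_axis(c(0, 0, 0), 10), "zero norm")

  plant <- test_plant()
  cl <- plant$cloud
  d <- leaf_descriptors(cl)
  out <- augment_rotate_leaf_pca(cl, leaf_id = 3, theta = 60,
                                 descriptors = d)
  li <- which(cl$instance == "LEAF_3")
  other <- setdiff(seq_len(n_points(cl)), li)
  expect_identical(out$positions[other, ], cl$positions[other, ])
  expect_lt(max_pairdist_change(cl$positions[li, ], out$positions[li, ]),
            1e-9)
  # the whole axis line is fixed: project base + t*axis for several t
  row <- d[d$leaf_id == 3, ]
  base <- c(row$base_x, row$base_y, row$base_z)
  axis <- c(row$axis_x, row$axis_y, row$axis_z)
  R2 <- rotation_about_axis(axis, 60)
  for (t in c(0, 0.05, 0.2)) {
    pt <- base + t * axis
    moved <- as.numeric(R2 %*% (pt - base)) + base
    expect_lt(max(abs(moved - pt)), 1e-12)
  }
  # theta = 0 is the identity
  idt <- augment_rotate_leaf_pca(cl, leaf_id = 3, theta = 0,
                                 descriptors = d)
  expect_lt(max(abs(idt$positions - cl$positions)), 1e-12)
})

test_that("leaf operations never alter the semantic label multiset", {
  cl <- test_plant()$cloud
  d <- leaf_descriptors(cl)
  outs <- list(augment_translate_leaves(cl, sigma_l = 0.3, seed = 1),
               augment_rotate_leaf_z(cl, seed = 1, descriptors = d),
               augment_rotate_leaf_pca(cl, seed = 1, descriptors = d))
  for (out in outs) {
    expect_identical(table(out$semantic), table(cl$semantic))
    expect_identical(out$instance, cl$instance)
  }
})

test_that("crossover swaps same-rank leaves between plants with exact
           alignment", {
  plants <- lapply(1:2, function(i)
    test_plant(seed = 30 + i, points = 2500))
  clouds <- lapply(plants, `[[`, "cloud")
  # color-tag each plant so transplanted points are traceable
  clouds[[1]]$colors[] <- 0.25
  clouds[[2]]$colors[] <- 0.75
  d_before <- lapply(clouds, leaf_descriptors)
  # no final resampling, so the grafted geometry can be inspected exactly
  res <- augment_crossover(clouds, n_c = 1, n_target = NULL, seed = 77)
  swaps <- attr(res, "swaps")
  expect_identical(nrow(swaps), 2L)
  r <- swaps$rank[1]
  expect_true(all(swaps$donor != swaps$receiver))
  for (j in 1:2) {
    out <- res[[j]]
    # leaf count conserved
    expect_identical(length(leaf_ids(out)), length(leaf_ids(clouds[[j]])))
    drow <- d_before[[j]]
    krep <- drow$leaf_id[drow$rank == r]
    li <- which(out$instance == paste0("LEAF_", krep))
    # the rank-r leaf now carries the other plant's color tag
    expect_true(all(abs(out$colors[li, 1] -
                          (if (j == 1) 0.75 else 0.25)) < 1e-12))
    # alignment: the graft puts a transplanted point exactly onto the
    # replaced leaf's base point (the donor's base maps there rigidly)
    old_base <- c(drow$base_x[drow$rank == r], drow$base_y[drow$rank == r],
                  drow$base_z[drow$rank == r])
    gap <- sqrt(rowSums(sweep(out$positions[li, , drop = FALSE], 2L,
                              old_base)^2))
    expect_lt(min(gap), 1e-6)
    d_after <- leaf_descriptors(out)
    arow <- d_after[d_after$leaf_id == krep, ]
    # and its phyllotactic orientation matches to 0.5 degrees
    ang <- phyllotactic_angle(
      c(drow$orient_x[drow$rank == r], drow$orient_y[drow$rank == r]),
      c(arow$orient_x, arow$orient_y))
    expect_lt(min(ang, 360 - ang), 0.5)
  }
  # with a size target, every output honors the fixed-size contract
  res2 <- augment_crossover(clouds, n_c = 2, n_target = 2200, seed = 78)
  expect_true(all(vapply(res2, n_points, 1L) == 2200L))
  for (j in 1:2) {
    expect_identical(length(leaf_ids(res2[[j]])),
                     length(leaf_ids(clouds[[j]])))
  }
})

test_that("crossover assignment is always a derangement and respects
           eligibility", {
  # no leaf ever returns to its own plant across many seeded runs
  for (s in 1:25) {
    perm <- withr::with_seed(s, plantaug:::random_derangement(4))
    expect_true(all(perm != 1:4))
  }
  # distinct-cultivar input is refused
  p1 <- test_plant(seed = 41, points = 1200)$cloud
  p2 <- test_plant(seed = 42, points = 1200)$cloud
  p2$meta$cultivar <- "Other"
  expect_error(augment_crossover(list(p1, p2), n_c = 1, n_target = 500),
               "cultivar")
  # requesting more rounds than swappable ranks performs what it can
  p2$meta$cultivar <- p1$meta$cultivar
  expect_warning(
    res <- augment_crossover(list(p1, p2), n_c = 50, n_target = 900,
                             seed = 3),
    "rounds possible")
  expect_true(attr(res, "n_rounds") < 50)
  expect_true(all(vapply(res, n_points, 1L) == 900L))
})
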