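reg <- brick_registry()

test_that("an empty layout voxelizes to an all-air grid", {
  g <- voxelize(brick_layout(), reg, 0.275)
  vr <- volume_report(g)
  expect_equal(vr$volume_cm3[vr$label != "air"], rep(0, 4))
  g10 <- voxel_grid(c(0, 0, 0), 0.275, array(0L, c(10L, 10L, 10L)))
  vr10 <- volume_report(g10)
  expect_equal(vr10$volume_cm3[vr10$label == "air"], 1000 * 0.275^3)
})

test_that("grid-aligned solid bricks have exact voxel volumes", {
  one <- brick_layout(list(placement("a", "full")))
  vr <- volume_report(voxelize(one, reg, 0.275, holes = FALSE))
  expect_equal(vr$volume_cm3[vr$label == "polyethylene"], 998.25)
  half <- brick_layout(list(placement("a", "half")))
  vrh <- volume_report(voxelize(half, reg, 0.275, holes = FALSE))
  expect_equal(vrh$volume_cm3[vrh$label == "polyethylene"], 499.125)
})

test_that("resolution must divide the lattice unit; overlaps are caught", {
  expect_error(voxelize(brick_layout(list(placement("a", "full"))), reg, 0.3),
               class = "bp_config_error")
})

test_that("label volumes partition the bounding volume", {
  lay <- parse_ldraw(generate_canonical_layout("mini_torso"), registry = reg)
  vr <- volume_report(voxelize(lay, reg, 0.275))
  expect_equal(sum(vr$volume_cm3), attr(vr, "total_cm3"))
})

test_that("voxel volumes converge to the analytical volumes at first order", {
  lay <- brick_layout(list(placement("a", "full", source_hole = 1L)))
  spec <- reg$full
  src <- spec$holes[spec$holes$kind == "source", ]
  conn <- spec$holes[spec$holes$kind == "connector", ]
  v_box <- prod(spec$dims)
  v_srchole <- sum(pi * src$radius^2 * src$depth)
  v_conn <- sum(pi * conn$radius^2 * conn$depth)
  v_rod <- pi * spec$rod$radius^2 * spec$rod$active_length
  a_box <- 2 * (spec$dims[1] * spec$dims[2] + spec$dims[1] * spec$dims[3] +
                spec$dims[2] * spec$dims[3])
  a_holes <- sum(2 * pi * src$radius * src$depth) +
             sum(2 * pi * conn$radius * conn$depth)
  a_rod <- 2 * pi * spec$rod$radius * spec$rod$active_length +
           2 * pi * spec$rod$radius^2

  errs <- c()
  for (res in c(0.275, 0.1375)) {
    vr <- volume_report(voxelize(lay, reg, res))
    err_poly <- abs(vr$volume_cm3[vr$label == "polyethylene"] -
                    (v_box - v_srchole - v_conn))
    err_rod <- abs(vr$volume_cm3[vr$label == "source"] - v_rod)
    expect_lte(err_poly, (a_box + a_holes) * res)
    expect_lte(err_rod, a_rod * res)
    errs <- c(errs, err_poly)
  }
  expect_lte(errs[2], errs[1])   # halving the resolution does not grow the error

  # at fine resolution the rod active volume is within 2 % of pi r^2 L
  vr <- volume_report(voxelize(lay, reg, 0.06875))
  expect_equal(vr$volume_cm3[vr$label == "source"], pi * 0.35^2 * 5.5,
               tolerance = 0.02)
})

test_that("rotated bricks rasterize to the same material volumes", {
  rotz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  a <- volume_report(voxelize(brick_layout(list(
    placement("a", "full", source_hole = 2L))), reg, 0.1375))
  b <- volume_report(voxelize(brick_layout(list(
    placement("a", "full", c(0L, 0L, 0L), rotz, 2L))), reg, 0.1375))
  expect_equal(a$volume_cm3, b$volume_cm3)
})

test_that("sampled points are inside their cylinder, cell, and voxel region", {
  lay <- brick_layout(list(placement("f1", "full", source_hole = 1L)))
  dist <- build_source_distribution(lay, reg)
  s <- sample_source_points(dist, n = 1000, seed = 11)
  expect_equal(nrow(s$points), 1000L)
  rec <- dist$records[1, ]
  r2 <- (s$points$x - rec$bx)^2 + (s$points$y - rec$by)^2
  expect_true(all(r2 <= rec$radius^2))
  expect_true(all(s$points$z >= 0 & s$points$z <= rec$active_length))
  # inside the assigned lattice cell
  u <- lattice_unit(reg)
  ent <- dist$entries[s$points$entry, ]
  expect_true(all(floor(s$points$z / u) == ent$ck))
  expect_gte(s$efficiency, pi / 4 * 0.9)
  # and inside exactly one analytic source region
  spec <- reg$full
  src <- spec$holes[spec$holes$kind == "source", ]
  n_in <- rep(0L, nrow(s$points))
  for (h in seq_len(nrow(src))) {
    hit <- (s$points$x - src$cx[h])^2 + (s$points$y - src$cy[h])^2 <=
      spec$rod$radius^2 & s$points$z >= 0 & s$points$z <= spec$rod$active_length
    n_in <- n_in + as.integer(hit)
  }
  expect_true(all(n_in == 1L))
})

test_that("seeded sampling is reproducible bit-for-bit", {
  lay <- brick_layout(list(
    placement("f1", "full", c(0L, 0L, 0L), source_hole = 1L),
    placement("h1", "half", c(6L, 0L, 0L), source_hole = 4L)))
  dist <- build_source_distribution(lay, reg)
  a <- sample_source_points(dist, n = 5000, seed = 20210828)
  b <- sample_source_points(dist, n = 5000, seed = 20210828)
  expect_identical(a, b)
  c2 <- sample_source_points(dist, n = 5000, seed = 1)
  expect_false(identical(a$points, c2$points))
})

test_that("per-entry counts match the sampling probabilities within 3 sigma", {
  lay <- brick_layout(list(placement("f1", "full", source_hole = 1L)))
  dist <- build_source_distribution(lay, reg)
  n <- 1e5
  s <- sample_source_points(dist, n = n, seed = 3)
  for (i in 1:2) {
    expect_lt(abs(s$counts[i] - n / 2), 3 * sqrt(n * 0.5 * 0.5))
  }
  # uniform axial distribution along the rod (Kolmogorov-Smirnov, alpha 0.01)
  ks <- stats::ks.test(s$points$z, "punif", 0, 5.5)
  expect_gt(ks$p.value, 0.01)

  mix <- brick_layout(list(
    placement("f1", "full", c(0L, 0L, 0L), source_hole = 1L),
    placement("h1", "half", c(6L, 0L, 0L), source_hole = 1L)))
  dmix <- build_source_distribution(mix, reg)
  smix <- sample_source_points(dmix, n = n, seed = 4)
  half_count <- sum(smix$counts[dmix$entries$brick == "half"])
  expect_lt(abs(half_count - n / 3), 3 * sqrt(n * (1 / 3) * (2 / 3)))
})
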