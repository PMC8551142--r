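test_that("default registry reproduces the phantom brick dimensions", {
  reg <- brick_registry()
  expect_equal(reg$full$dims, c(16.5, 11, 5.5))
  expect_equal(reg$half$dims, c(16.5, 11, 2.75))
  expect_equal(reg$full$seg, c(6L, 4L, 2L))
  expect_equal(reg$half$seg, c(6L, 4L, 1L))
  expect_equal(sum(reg$full$holes$kind == "source"), 4L)
  expect_equal(sum(reg$half$holes$kind == "source"), 4L)
  # rod active sections start flush with the front face and fit the hole
  for (t in reg) {
    expect_lte(t$rod$active_length + t$rod$plug_length,
               max(t$holes$depth[t$holes$kind == "source"]) + 1e-12)
    expect_lte(t$rod$radius, min(t$holes$radius[t$holes$kind == "source"]))
  }
})

test_that("brick dimensions must be integer multiples of the lattice unit", {
  cfg <- default_config()
  cfg$bricks$full$dims <- c(16.5, 11, 5.0)
  expect_error(brick_registry(cfg), class = "bp_config_error")
})

test_that("lattice unit is the minimum brick edge", {
  expect_equal(lattice_unit(brick_registry()), 2.75)
  cfg <- default_config()
  cfg$bricks$full$dims <- c(2, 2, 2)   # synthetic 2x2x2 and 2x2x1 bricks
  cfg$bricks$half$dims <- c(2, 2, 1)
  cfg$holes$source$dx <- 0.5           # shrink the hole pattern to fit
  cfg$holes$source$dy <- 0.5
  cfg$holes$source$radius <- 0.2
  cfg$rod$radius <- 0.1
  expect_equal(lattice_unit(brick_registry(cfg)), 1)
  cfg$bricks$full$dims <- c(3, 3, 3)   # two identical cubes of side s
  cfg$bricks$half$dims <- c(3, 3, 3)
  expect_equal(lattice_unit(brick_registry(cfg)), 3)
})

test_that("a full brick splits into 48 segments and a half brick into 24", {
  reg <- brick_registry()
  s_full <- segment_brick(placement("b1", "full"), reg)
  expect_equal(nrow(s_full), 48L)
  expect_equal(range(s_full$ci), c(0L, 5L))
  expect_equal(range(s_full$cj), c(0L, 3L))
  expect_equal(range(s_full$ck), c(0L, 1L))
  expect_equal(anyDuplicated(s_full$universe), 0L)
  expect_equal(nrow(segment_brick(placement("b2", "half"), reg)), 24L)
})

test_that("rotating a full brick 90 degrees about z gives a 4 x 6 x 2 footprint", {
  reg <- brick_registry()
  rotz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  p <- placement("b1", "full", c(0L, 0L, 0L), rotz)
  segs <- segment_brick(p, reg)
  expect_equal(range(segs$ci), c(0L, 3L))
  expect_equal(range(segs$cj), c(0L, 5L))
  expect_equal(range(segs$ck), c(0L, 1L))
  expect_equal(cells_of(segs), rasterize_brick_cells(p, reg))
})

test_that("segmentation equals brute-force rasterization for random poses", {
  reg <- brick_registry()
  rots <- cube_rotations()
  set.seed(101)
  for (i in 1:30) {
    p <- placement(sprintf("b%d", i),
                   sample(c("full", "half"), 1L),
                   sample(-5:5, 3L, replace = TRUE),
                   rots[[sample.int(24L, 1L)]])
    expect_equal(cells_of(segment_brick(p, reg)),
                 rasterize_brick_cells(p, reg))
  }
})

test_that("segment map counts, extents and disjointness are exact", {
  reg <- brick_registry()
  empty <- build_segment_map(brick_layout(), reg)
  expect_equal(nrow(empty$cells), 0L)
  expect_equal(empty$extents, c(0L, 0L, 0L))

  one <- build_segment_map(brick_layout(list(placement("a", "full"))), reg)
  expect_equal(nrow(one$cells), 48L)
  expect_equal(one$extents, c(6L, 4L, 2L))

  two <- brick_layout(list(placement("a", "full", c(0L, 0L, 0L)),
                           placement("b", "full", c(0L, 0L, 2L))))
  sm <- build_segment_map(two, reg)
  expect_equal(nrow(sm$cells), 96L)
  expect_equal(sm$extents, c(6L, 4L, 4L))
  expect_equal(anyDuplicated(paste(sm$cells$ci, sm$cells$cj, sm$cells$ck)), 0L)
  # disjoint union of the two enumerated cell sets
  all_cells <- rbind(rasterize_brick_cells(two$placements[[1]], reg),
                     rasterize_brick_cells(two$placements[[2]], reg))
  expect_equal(cells_of(sm$cells),
               all_cells[order(all_cells[, 1], all_cells[, 2], all_cells[, 3]), ])
})

test_that("collisions are detected with the exact shared cell sets", {
  reg <- brick_registry()
  same <- brick_layout(list(placement("a", "full"), placement("b", "full")))
  conf <- detect_collisions(same, reg)
  expect_length(conf, 1L)
  expect_equal(nrow(conf[[1]]$cells), 48L)
  expect_error(build_segment_map(same, reg), class = "bp_collision_error")

  apart <- brick_layout(list(placement("a", "full", c(0L, 0L, 0L)),
                             placement("b", "full", c(6L, 0L, 0L))))
  expect_length(detect_collisions(apart, reg), 0L)

  overlap <- brick_layout(list(placement("a", "full", c(0L, 0L, 0L)),
                               placement("b", "half", c(0L, 0L, 1L))))
  conf <- detect_collisions(overlap, reg)
  expect_length(conf, 1L)
  expect_equal(nrow(conf[[1]]$cells), 24L)
  expect_setequal(c(conf[[1]]$a, conf[[1]]$b), c("a", "b"))
})

test_that("solid mass is density times summed brick volume", {
  reg <- brick_registry()
  expect_equal(layout_mass(brick_layout(list(placement("a", "full"))), reg, 1.0),
               0.99825)
  expect_equal(layout_mass(brick_layout(), reg, 1.0), 0)
  big <- brick_layout(c(
    lapply(1:68, function(i) placement(sprintf("f%d", i), "full", c(7L * i, 0L, 0L))),
    lapply(1:4, function(i) placement(sprintf("h%d", i), "half", c(-7L * i, 0L, 0L)))))
  expect_equal(layout_mass(big, reg, 1.0), 69.8775)
  expect_error(layout_mass(big, reg, 0), class = "bp_config_error")
})

test_that("the orientation group has exactly 24 elements and is closed", {
  rots <- cube_rotations()
  expect_length(rots, 24L)
  keys <- vapply(rots, function(m) paste(m, collapse = " "), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (m in rots) expect_true(is_orientation(m))
  set.seed(7)
  for (i in 1:50) {
    a <- rots[[sample.int(24L, 1L)]]
    b <- rots[[sample.int(24L, 1L)]]
    expect_true(is_orientation(a %*% b))
    expect_true(paste(a %*% b, collapse = " ") %in% keys)
  }
  # reflections are rejected
  expect_false(is_orientation(diag(c(-1, 1, 1))))
  expect_false(is_orientation(matrix(0.5, 3, 3)))
})

test_that("occupancy of collision-free layouts is 48 n_full + 24 n_half", {
  reg <- brick_registry()
  for (seed in 1:20) {
    lay <- random_layout(5L, seed, reg)
    counts <- table(vapply(lay$placements, function(p) p$brick, character(1)))
    n_full <- if ("full" %in% names(counts)) counts[["full"]] else 0L
    n_half <- if ("half" %in% names(counts)) counts[["half"]] else 0L
    sm <- build_segment_map(lay, reg)
    expect_equal(nrow(sm$cells), 48L * n_full + 24L * n_half)
  }
})

test_that("the lattice unit divides every default brick dimension", {
  reg <- brick_registry()
  u <- lattice_unit(reg)
  for (t in reg) {
    expect_equal(t$dims %% u, c(0, 0, 0), tolerance = 1e-12)
  }
})
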