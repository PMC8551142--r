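# Shared fixtures built in code.

# Sequential rejection sampler for random collision-free layouts: random
# brick type, orientation (all 24 rotations), lattice index and optional
# source hole; a candidate is kept only if its cell set is disjoint from the
# cells already occupied.
random_layout <- function(n, seed, registry = brick_registry(), p_source = 0.5,
                          span = 6L) {
  set.seed(seed)
  rots <- cube_rotations()
  placements <- list()
  occupied <- character(0)
  tries <- 0L
  while (length(placements) < n && tries < 100L * n) {
    tries <- tries + 1L
    brick <- sample(c("full", "half"), 1L)
    R <- rots[[sample.int(24L, 1L)]]
    idx <- sample.int(2L * span + 1L, 3L, replace = TRUE) - span - 1L
    hole <- if (stats::runif(1) < p_source) sample.int(4L, 1L) else NA_integer_
    p <- placement(sprintf("r%03d", length(placements) + 1L), brick, idx, R, hole)
    segs <- segment_brick(p, registry)
    keys <- paste(segs$ci, segs$cj, segs$ck)
    if (any(keys %in% occupied)) next
    occupied <- c(occupied, keys)
    placements[[length(placements) + 1L]] <- p
  }
  brick_layout(placements)
}

# Independent brute-force oracle for brick segmentation: sample the rotated
# brick volume on a fine grid of interior points and collect the lattice
# cells those world points fall into.
rasterize_brick_cells <- function(p, registry, nsub = 4L) {
  u <- lattice_unit(registry)
  dims <- registry[[p$brick]]$dims
  R <- p$orientation
  box_min <- vapply(1:3, function(k) sum(pmin(R[k, ] * dims, 0)), numeric(1))
  p0 <- p$index * u - box_min
  step <- u / nsub
  g <- as.matrix(expand.grid(
    x = seq(step / 2, dims[1] - step / 2, by = step),
    y = seq(step / 2, dims[2] - step / 2, by = step),
    z = seq(step / 2, dims[3] - step / 2, by = step)))
  w <- g %*% t(R)
  w <- sweep(w, 2, p0, "+")
  cells <- unique(floor(w / u + 1e-9))
  cells[order(cells[, 1], cells[, 2], cells[, 3]), , drop = FALSE]
}

cells_of <- function(segs) {
  m <- as.matrix(segs[, c("ci", "cj", "ck")])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Split serialized deck text into its three card blocks.
deck_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  idx <- cumsum(lines == "")
  list(cells = lines[idx == 0 & lines != ""][-1],   # drop the title card
       surfaces = lines[idx == 1 & lines != ""],
       data = lines[idx == 2 & lines != ""])
}
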