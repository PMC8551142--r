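# Voxel label codes used by the oracle grid.
VOXEL_LABELS <- c(air = 0L, polyethylene = 1L, hole = 2L, source = 3L, plug = 4L)

#' Construct a voxel grid
#'
#' @param origin World coordinate (cm) of the grid min corner.
#' @param resolution Voxel edge length in cm.
#' @param labels 3-D integer array of region codes (0 air, 1 polyethylene,
#'   2 hole void, 3 source active, 4 plug).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, resolution, labels) {
  if (resolution <= 0) bp_abort("bp_config_error", "voxel resolution must be > 0")
  if (!all(labels %in% VOXEL_LABELS)) {
    bp_abort("bp_config_error", "voxel labels outside the known label set")
  }
  structure(list(origin = as.numeric(origin), resolution = resolution,
                 labels = labels), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %.5g cm\n",
              d[1], d[2], d[3], x$resolution))
  invisible(x)
}

# Broadcast a vector along one axis of a 3-D array of dimension dim3.
vec3d <- function(v, axis, dim3) {
  if (axis == 1L) return(array(v, dim3))
  if (axis == 2L) return(aperm(array(v, dim3[c(2L, 1L, 3L)]), c(2L, 1L, 3L)))
  aperm(array(v, dim3[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Rasterize a layout to a voxel grid (test oracle)
#'
#' Implementation-independent check of the analytical geometry: every voxel
#' is labelled by evaluating the constructive geometry (brick boxes minus
#' hole cylinders, plus rod active/plug cylinders) at the voxel centre.
#' Centre-point labelling gives a first-order volume error bounded by
#' (surface area x resolution) per region.
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @param resolution Voxel edge in cm; must divide the lattice unit evenly
#'   (e.g. 0.275, 0.1375, 0.06875).
#' @param holes If `FALSE`, bricks are rasterized as solid boxes.
#' @return A [voxel_grid()] covering the layout's lattice bounding box.
#' @export
voxelize <- function(layout, registry = brick_registry(), resolution = 0.275,
                     holes = TRUE) {
  u <- lattice_unit(registry)
  m <- u / resolution
  if (abs(m - round(m)) > 1e-9) {
    bp_abort("bp_config_error", sprintf(
      "resolution %.6g cm does not divide the %.6g cm lattice unit evenly",
      resolution, u))
  }
  m <- as.integer(round(m))
  smap <- build_segment_map(layout, registry)
  if (any(smap$extents == 0L)) {
    return(voxel_grid(c(0, 0, 0), resolution, array(0L, c(0L, 0L, 0L))))
  }
  dim3 <- smap$extents * m
  labels <- array(0L, dim3)
  claimed <- array(FALSE, dim3)
  origin <- smap$origin * u

  for (p in layout$placements) {
    spec <- registry[[p$brick]]
    R <- p$orientation
    p0 <- placement_origin(p, registry)
    fdims <- rot_box_dims(R, spec$dims)            # world-frame box extents
    lo_vox <- as.integer(round((p$index * u - origin) / resolution))
    n_vox <- as.integer(round(fdims / resolution))
    sub <- lapply(1:3, function(a) lo_vox[a] + seq_len(n_vox[a]))

    if (any(claimed[sub[[1]], sub[[2]], sub[[3]]])) {
      bp_abort("bp_collision_error", sprintf(
        "voxel oracle: placement '%s' overlaps a previously rasterized brick", p$pid))
    }
    claimed[sub[[1]], sub[[2]], sub[[3]]] <- TRUE

    # world-axis centre coordinates of the sub-grid, then brick-local
    # coordinates: q_j depends on exactly one world axis (signed permutation)
    wc <- lapply(1:3, function(a) origin[a] + (sub[[a]] - 0.5) * resolution)
    Rt <- t(R)
    q <- vector("list", 3L)   # q[[j]]: local coord j as 3-D array
    for (j in 1:3) {
      a <- which(Rt[j, ] != 0)
      q[[j]] <- vec3d(Rt[j, a] * (wc[[a]] - p0[a]), a, n_vox)
    }

    lab <- array(VOXEL_LABELS[["polyethylene"]], n_vox)
    if (holes) {
      hs <- spec$holes
      for (hidx in seq_len(nrow(hs))) {
        hr <- hs[hidx, ]
        ax <- c(hr$ax, hr$ay, hr$az)
        kk <- which(abs(ax) > 0.5)
        pp <- setdiff(1:3, kk)
        axial <- ax[kk] * (q[[kk]] - hr[[c("cx", "cy", "cz")[kk]]])
        r2 <- (q[[pp[1]]] - hr[[c("cx", "cy", "cz")[pp[1]]]])^2 +
              (q[[pp[2]]] - hr[[c("cx", "cy", "cz")[pp[2]]]])^2
        inhole <- r2 <= hr$radius^2 & axial >= 0 & axial < hr$depth
        lab[inhole] <- VOXEL_LABELS[["hole"]]
        if (hr$kind == "source" && !is.na(p$source_hole) && hr$id == p$source_hole) {
          rod <- spec$rod
          inrod <- r2 <= rod$radius^2 & axial >= 0
          lab[inrod & axial < rod$active_length] <- VOXEL_LABELS[["source"]]
          if (rod$plug_length > 0) {
            lab[inrod & axial >= rod$active_length &
                axial < rod$active_length + rod$plug_length] <- VOXEL_LABELS[["plug"]]
          }
        }
      }
    }
    labels[sub[[1]], sub[[2]], sub[[3]]] <- lab
  }
  voxel_grid(origin, resolution, labels)
}

#' Per-label volumes of a voxel grid
#'
#' @param grid A [voxel_grid()].
#' @return Data frame with `label`, `voxels` and `volume_cm3` (count times
#'   resolution cubed); the volumes partition the grid bounding volume,
#'   attached as attribute `total_cm3`.
#' @export
volume_report <- function(grid) {
  counts <- vapply(VOXEL_LABELS, function(code) sum(grid$labels == code), numeric(1))
  out <- data.frame(label = names(VOXEL_LABELS), voxels = unname(counts),
                    volume_cm3 = unname(counts) * grid$resolution^3,
                    stringsAsFactors = FALSE)
  attr(out, "total_cm3") <- length(grid$labels) * grid$resolution^3
  out
}

#' Export a voxel grid for inspection
#'
#' Writes the mid-grid slice perpendicular to each axis as three CSV files
#' (`slice_x.csv`, `slice_y.csv`, `slice_z.csv`) plus a plain-text header
#' describing origin, resolution and dimensions.
#'
#' @param grid A [voxel_grid()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_voxel_slices <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$labels)
  if (any(d == 0L)) bp_abort("bp_geometry_error", "empty voxel grid")
  paths <- character(0)
  mid <- pmax(1L, d %/% 2L)
  slices <- list(x = grid$labels[mid[1], , ], y = grid$labels[, mid[2], ],
                 z = grid$labels[, , mid[3]])
  for (nm in names(slices)) {
    p <- file.path(dir, sprintf("slice_%s.csv", nm))
    utils::write.table(slices[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  hdr <- file.path(dir, "grid_header.txt")
  writeLines(c(sprintf("origin_cm: %s", paste(fmt_num(grid$origin), collapse = " ")),
               sprintf("resolution_cm: %s", fmt_num(grid$resolution)),
               sprintf("dims: %s", paste(d, collapse = " ")),
               sprintf("labels: %s", paste(sprintf("%d=%s", VOXEL_LABELS,
                                                   names(VOXEL_LABELS)),
                                           collapse = " "))), hdr)
  invisible(c(paths, hdr))
}

#' Monte-Carlo sample the source distribution (oracle)
#'
#' Draws `n` accepted source positions from a [build_source_distribution()]
#' by the same scheme the SDEF cards describe: pick an entry from the
#' discrete probability list, sample uniformly in its segment-clipped
#' bounding box, and reject points outside the rod cylinder.  Seeded and
#' bit-for-bit reproducible.
#'
#' @param distribution A `source_distribution`.
#' @param records Unused (interface symmetry with the SDEF emitter).
#' @param n Number of accepted points.
#' @param seed RNG seed.
#' @return List with `points` (data frame `entry, x, y, z`) and `counts`
#'   (accepted points per entry, in entry order), plus acceptance `efficiency`.
#' @export
sample_source_points <- function(distribution, records = NULL, n,
                                 seed = default_config()$sampling$seed) {
  if (n <= 0) bp_abort("bp_config_error", "n must be positive")
  entries <- distribution$entries
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, entries$prob))
  attempts <- 0L
  accepted <- 0L
  pts <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    m <- counts[i]
    if (m == 0L) next
    e <- entries[i, ]
    axis <- c(e$ax, e$ay, e$az)
    k <- which(abs(axis) > 0.5)
    perp <- setdiff(1:3, k)
    ctr <- c(e$bx, e$by, e$bz)
    lo <- c(e$x0, e$y0, e$z0)
    hi <- c(e$x1, e$y1, e$z1)
    got <- matrix(numeric(0), ncol = 3)
    att <- 0L
    while (nrow(got) < m) {
      b <- max(64L, ceiling((m - nrow(got)) / 0.7))
      att <- att + b
      cand <- cbind(stats::runif(b, lo[1], hi[1]),
                    stats::runif(b, lo[2], hi[2]),
                    stats::runif(b, lo[3], hi[3]))
      ok <- (cand[, perp[1]] - ctr[perp[1]])^2 +
            (cand[, perp[2]] - ctr[perp[2]])^2 <= e$radius^2
      got <- rbind(got, cand[ok, , drop = FALSE])
      if (att > 1000L && nrow(got) / att < 0.1) {
        bp_abort("bp_geometry_error",
                 "source sampling rejection efficiency below 10 %; check hole/rod geometry")
      }
    }
    attempts <- attempts + att
    accepted <- accepted + nrow(got)
    got <- got[seq_len(m), , drop = FALSE]
    pts[[i]] <- data.frame(entry = i, x = got[, 1], y = got[, 2], z = got[, 3])
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  rownames(points) <- NULL
  list(points = points, counts = counts, efficiency = accepted / attempts)
}
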