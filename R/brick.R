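#' Build the brick type registry
#'
#' Constructs the dimensioned templates of the two Saint Petersburg phantom
#' brick types from a configuration: the full brick (16.5 x 11 x 5.5 cm,
#' segmented 6 x 4 x 2) and the half brick (16.5 x 11 x 2.75 cm, 6 x 4 x 1).
#' Each template carries its four front-face source drill holes, the
#' connector blind holes on the side faces, and the rod-source dimensions.
#'
#' Local brick frame: x spans 16.5 cm, y spans 11 cm, z spans the thickness;
#' the front face (the 16.5 x 11 cm face that takes the rod sources) is the
#' z = 0 plane and holes are drilled along +z.
#'
#' @param config Configuration list, see [default_config()].
#' @return An object of class `brick_registry`: a named list of brick specs
#'   with the lattice unit attached as attribute `unit`.
#' @export
#' @examples
#' reg <- brick_registry()
#' reg$full$dims      # 16.5 11 5.5
#' reg$half$seg       # 6 4 1
#' lattice_unit(reg)  # 2.75
brick_registry <- function(config = default_config()) {
  validate_config(config)
  dims_list <- lapply(config$bricks, function(b) as.numeric(b$dims))
  unit <- min(unlist(dims_list))
  types <- list()
  thick_max <- max(vapply(dims_list, function(d) d[3], numeric(1)))
  for (id in names(dims_list)) {
    dims <- dims_list[[id]]
    n <- dims / unit
    if (max(abs(n - round(n))) > 1e-9) {
      bp_abort("bp_config_error", sprintf(
        "brick '%s' dimensions (%s) cm are not integer multiples of the %.6g cm lattice unit",
        id, paste(format(dims), collapse = ", "), unit))
    }
    seg <- as.integer(round(n))

    hs <- config$holes$source
    depth <- if (is.na(hs$depth)) dims[3] else hs$depth
    if (depth > dims[3] + 1e-9) {
      bp_abort("bp_config_error", sprintf(
        "source hole depth %.6g cm exceeds brick '%s' thickness %.6g cm", depth, id, dims[3]))
    }
    cx <- dims[1] / 2
    cy <- dims[2] / 2
    # hole numbering: 1 = (-dx,-dy), 2 = (+dx,-dy), 3 = (-dx,+dy), 4 = (+dx,+dy)
    src <- data.frame(
      id = 1:4, kind = "source",
      cx = cx + c(-1, 1, -1, 1) * hs$dx,
      cy = cy + c(-1, -1, 1, 1) * hs$dy,
      cz = 0,
      ax = 0, ay = 0, az = 1,
      radius = hs$radius, depth = depth,
      stringsAsFactors = FALSE
    )
    if (any(src$cx - hs$radius < 0 | src$cx + hs$radius > dims[1] |
            src$cy - hs$radius < 0 | src$cy + hs$radius > dims[2])) {
      bp_abort("bp_config_error",
               sprintf("source holes fall outside the front face of brick '%s'", id))
    }
    hc <- config$holes$connector
    cdepth <- min(hc$depth, dims[1] / 2, dims[2] / 2)
    conn <- data.frame(
      id = 5:8, kind = "connector",
      cx = c(0, dims[1], cx, cx),
      cy = c(cy, cy, 0, dims[2]),
      cz = dims[3] / 2,
      ax = c(1, -1, 0, 0), ay = c(0, 0, 1, -1), az = 0,
      radius = hc$radius, depth = cdepth,
      stringsAsFactors = FALSE
    )

    plug <- config$rod$plug_length
    active <- if (is.na(config$rod$active_length)) dims[3] - plug else config$rod$active_length
    if (active <= 0) {
      bp_abort("bp_config_error", sprintf("rod active length is not positive for brick '%s'", id))
    }
    if (active + plug > depth + 1e-9) {
      bp_abort("bp_config_error", sprintf(
        "rod active + plug length %.6g cm exceeds the %.6g cm source hole depth of brick '%s'",
        active + plug, depth, id))
    }
    rod <- list(radius = config$rod$radius, active_length = active, plug_length = plug)

    types[[id]] <- structure(
      list(id = id, dims = dims, seg = seg,
           holes = rbind(src, conn), rod = rod,
           volume = prod(dims),
           source_weight = dims[3] / thick_max),
      class = "brick_spec")
  }
  structure(types, unit = unit, class = "brick_registry")
}

#' Lattice unit length
#'
#' The spacing of the placement/segmentation grid: the smallest edge length
#' over all brick types (2.75 cm, the half-brick thickness, for the default
#' registry).
#'
#' @param registry A [brick_registry()].
#' @return Length in cm.
#' @export
lattice_unit <- function(registry) {
  if (length(registry) == 0L) {
    bp_abort("bp_config_error", "empty brick registry has no lattice unit")
  }
  u <- attr(registry, "unit")
  if (is.null(u)) u <- min(unlist(lapply(registry, function(t) t$dims)))
  u
}

#' @export
print.brick_registry <- function(x, ...) {
  cat(sprintf("<brick_registry> %d brick types, lattice unit %.4g cm\n",
              length(x), lattice_unit(x)))
  for (t in x) {
    cat(sprintf("  %-5s %.4g x %.4g x %.4g cm, %d x %d x %d segments, %d source holes\n",
                t$id, t$dims[1], t$dims[2], t$dims[3],
                t$seg[1], t$seg[2], t$seg[3], sum(t$holes$kind == "source")))
  }
  invisible(x)
}

#' Create a brick placement
#'
#' A placement is a brick's pose on the lattice: the integer index of the
#' minimum-corner cell of its (rotated) footprint, one of the 24 proper cube
#' rotations, and optionally which of the four source drill holes carries a
#' rod source.  At most one source per brick.
#'
#' @param pid Stable placement identifier (unique within a layout).
#' @param brick Brick type id (`"full"` or `"half"`).
#' @param index Integer lattice index (i, j, k) of the min-corner cell.
#' @param orientation 3x3 signed permutation matrix with determinant +1.
#' @param source_hole Hole number 1-4, or `NA` for no source.
#' @return An object of class `bp_placement`.
#' @export
placement <- function(pid, brick, index = c(0L, 0L, 0L),
                      orientation = diag(3L), source_hole = NA_integer_) {
  if (!is_orientation(orientation)) {
    bp_abort("bp_orientation_error",
             sprintf("placement '%s': orientation is not one of the 24 proper cube rotations", pid))
  }
  if (length(index) != 3L || max(abs(index - round(index))) > 1e-9) {
    bp_abort("bp_config_error", sprintf("placement '%s': index must be 3 integers", pid))
  }
  if (!is.na(source_hole) && !(source_hole %in% 1:4)) {
    bp_abort("bp_config_error",
             sprintf("placement '%s': source hole must be 1-4 or NA", pid))
  }
  structure(list(pid = as.character(pid), brick = brick,
                 index = as.integer(round(index)),
                 orientation = round(orientation),
                 source_hole = as.integer(source_hole)),
            class = "bp_placement")
}

#' Create a brick layout
#'
#' An ordered collection of placements with unique ids.
#'
#' @param placements List of [placement()] objects.
#' @return An object of class `brick_layout`.
#' @export
brick_layout <- function(placements = list()) {
  if (inherits(placements, "bp_placement")) placements <- list(placements)
  pids <- vapply(placements, function(p) p$pid, character(1))
  if (anyDuplicated(pids)) {
    bp_abort("bp_config_error", sprintf("duplicate placement ids: %s",
             paste(unique(pids[duplicated(pids)]), collapse = ", ")))
  }
  structure(list(placements = placements), class = "brick_layout")
}

#' @export
print.brick_layout <- function(x, ...) {
  n <- length(x$placements)
  types <- vapply(x$placements, function(p) p$brick, character(1))
  nsrc <- sum(!is.na(vapply(x$placements, function(p) p$source_hole, integer(1))))
  cat(sprintf("<brick_layout> %d placements (%s), %d with rod sources\n", n,
              paste(sprintf("%d %s", as.integer(table(types)), names(table(types))),
                    collapse = ", "), nsrc))
  invisible(x)
}

#' @export
length.brick_layout <- function(x) length(x$placements)

layout_counts <- function(layout) {
  types <- vapply(layout$placements, function(p) p$brick, character(1))
  c(full = sum(types == "full"), half = sum(types == "half"))
}

# World coordinate (cm) of a placement's brick-local origin: the min corner
# of the rotated box sits at the placement index cell corner.
placement_origin <- function(p, registry) {
  u <- lattice_unit(registry)
  dims <- registry[[p$brick]]$dims
  p$index * u - rot_box_min(p$orientation, dims)
}

#' Decompose a placed brick into unit lattice segments
#'
#' Splits a placement into its cubic (2.75 cm)^3 segments: 6 x 4 x 2 = 48
#' for a full brick, 6 x 4 x 1 = 24 for a half brick.  Each segment records
#' the local segment index within the brick, the global lattice cell it
#' occupies, and the universe id of the corresponding template sub-volume.
#'
#' @param p A [placement()].
#' @param registry A [brick_registry()].
#' @param plan A [numbering_plan()] supplying segment universe ids.
#' @return A data frame with one row per segment: `pid`, local indices
#'   `la, lb, lc` (0-based), global cell `ci, cj, ck`, `universe`, and the
#'   orientation key `okey`.
#' @export
#' @examples
#' reg <- brick_registry()
#' nrow(segment_brick(placement("b1", "full"), reg))  # 48
segment_brick <- function(p, registry, plan = numbering_plan()) {
  spec <- registry[[p$brick]]
  if (is.null(spec)) {
    bp_abort("bp_config_error", sprintf("unknown brick type '%s'", p$brick))
  }
  sc <- spec$seg
  loc <- as.matrix(expand.grid(la = 0:(sc[1] - 1L), lb = 0:(sc[2] - 1L),
                               lc = 0:(sc[3] - 1L)))
  centers <- loc + 0.5                       # local segment centres, lattice units
  R <- p$orientation
  rot <- centers %*% t(R)                    # row-wise R %*% centre
  mins <- apply(rot, 2, min) - 0.5
  rel <- round(sweep(rot - 0.5, 2, mins, "-"))
  cells <- sweep(rel, 2, p$index, "+")
  ubase <- plan$segment_universe[[p$brick]]
  if (is.null(ubase)) {
    bp_abort("bp_config_error",
             sprintf("numbering plan has no segment universe base for brick type '%s'", p$brick))
  }
  ord <- loc[, 1] + sc[1] * loc[, 2] + sc[1] * sc[2] * loc[, 3]
  data.frame(pid = p$pid,
             la = loc[, 1], lb = loc[, 2], lc = loc[, 3],
             ci = as.integer(cells[, 1]), cj = as.integer(cells[, 2]),
             ck = as.integer(cells[, 3]),
             universe = as.integer(ubase + ord),
             okey = orientation_key(R),
             stringsAsFactors = FALSE)
}

layout_segments <- function(layout, registry, plan = numbering_plan()) {
  if (length(layout$placements) == 0L) {
    return(data.frame(pid = character(0), la = integer(0), lb = integer(0),
                      lc = integer(0), ci = integer(0), cj = integer(0),
                      ck = integer(0), universe = integer(0),
                      okey = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(layout$placements, segment_brick,
                        registry = registry, plan = plan))
}

#' Detect colliding placements
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @return A list of conflicts, each a list with elements `a`, `b` (the two
#'   placement ids) and `cells` (matrix of shared lattice cells).  Empty if
#'   and only if all placements occupy pairwise-disjoint cell sets.
#' @export
detect_collisions <- function(layout, registry) {
  segs <- layout_segments(layout, registry)
  if (nrow(segs) == 0L) return(list())
  key <- paste(segs$ci, segs$cj, segs$ck)
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) == 0L) return(list())
  conflicts <- list()
  sub <- segs[key %in% dup_keys, , drop = FALSE]
  subkey <- paste(sub$ci, sub$cj, sub$ck)
  pairs <- list()
  for (k in dup_keys) {
    pids <- sub$pid[subkey == k]
    cb <- utils::combn(sort(unique(pids)), 2L)
    for (col in seq_len(ncol(cb))) {
      pk <- paste(cb[1, col], cb[2, col], sep = "\r")
      pairs[[pk]] <- rbind(pairs[[pk]],
                           as.matrix(sub[subkey == k, c("ci", "cj", "ck")])[1, , drop = FALSE])
    }
  }
  for (pk in sort(names(pairs))) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    cells <- unique(pairs[[pk]])
    rownames(cells) <- NULL
    conflicts[[length(conflicts) + 1L]] <- list(a = ab[1], b = ab[2], cells = cells)
  }
  conflicts
}

#' Build the segment occupancy map of a layout
#'
#' Maps every occupied 2.75 cm lattice cell to its (placement, segment
#' universe, rotation).  Overlapping placements are a collision error.
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @param plan A [numbering_plan()].
#' @return An object of class `segment_map`: list with `cells` (data frame as
#'   from [segment_brick()]), `origin` (min occupied cell index), `extents`
#'   (cell counts per axis, `c(0,0,0)` when empty), `background_universe`,
#'   and `unit` (cm).
#' @export
build_segment_map <- function(layout, registry, plan = numbering_plan()) {
  segs <- layout_segments(layout, registry, plan)
  if (nrow(segs) > 0L) {
    key <- paste(segs$ci, segs$cj, segs$ck)
    if (anyDuplicated(key)) {
      conf <- detect_collisions(layout, registry)
      desc <- vapply(conf, function(cf)
        sprintf("%s/%s (%d cells)", cf$a, cf$b, nrow(cf$cells)), character(1))
      bp_abort("bp_collision_error",
               sprintf("overlapping placements: %s", paste(desc, collapse = "; ")),
               conflicts = conf)
    }
    origin <- c(min(segs$ci), min(segs$cj), min(segs$ck))
    extents <- c(max(segs$ci), max(segs$cj), max(segs$ck)) - origin + 1L
  } else {
    origin <- c(0L, 0L, 0L)
    extents <- c(0L, 0L, 0L)
  }
  structure(list(cells = segs, origin = as.integer(origin),
                 extents = as.integer(extents),
                 background_universe = plan$background_universe,
                 unit = lattice_unit(registry)),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d occupied cells, extents %d x %d x %d (unit %.4g cm)\n",
              nrow(x$cells), x$extents[1], x$extents[2], x$extents[3], x$unit))
  invisible(x)
}

#' Solid mass of a layout
#'
#' Mass under the solid-brick approximation: density times the sum of brick
#' box volumes, ignoring the drill-hole voids (hole dimensions are
#' configuration conventions, so the mass is reported for the solid shape).
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @param density Mass density in g/cm3.
#' @return Mass in kg.
#' @export
#' @examples
#' reg <- brick_registry()
#' layout_mass(brick_layout(list(placement("b1", "full"))), reg, 1.0)  # 0.99825
layout_mass <- function(layout, registry, density) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    bp_abort("bp_config_error", "density must be a single positive number")
  }
  vol <- sum(vapply(layout$placements,
                    function(p) registry[[p$brick]]$volume, numeric(1)))
  density * vol / 1000
}
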