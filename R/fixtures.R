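# Canonical layout fixtures.  The 70 kg stretcher arrangement is a frozen
# convention of this package: the historical configuration is documented
# only by its brick counts (68 full + 4 half), so the lying-figure
# arrangement below realises those counts with legs, hips, torso, arms and
# head on the lattice, half bricks as hands and feet, and a rod source in
# hole 1 of every brick (homogeneous calibration distribution).

canonical_fixture_names <- function() {
  c("p70_stretcher", "mini_torso", "single_full", "single_half")
}

p70_placements <- function() {
  rows <- list()
  add <- function(brick, i, j, k, hole = 1L, orient = diag(3L)) {
    rows[[length(rows) + 1L]] <<- placement(
      pid = sprintf("p%03d", length(rows) + 1L), brick = brick,
      index = c(i, j, k), orientation = orient, source_hole = hole)
  }
  for (x in seq(0, 30, by = 6)) for (y in c(2L, 6L)) for (z in c(0L, 2L)) {
    add("full", x, y, z)                                   # legs (24)
  }
  for (y in c(0L, 4L, 8L)) for (z in c(0L, 2L)) {
    add("full", 36L, y, z)                                 # hips (6)
  }
  for (x in c(42L, 48L, 54L)) for (y in c(0L, 4L, 8L)) for (z in c(0L, 2L)) {
    add("full", x, y, z)                                   # torso (18)
  }
  for (x in c(36L, 42L, 48L, 54L)) for (y in c(-4L, 12L)) for (z in c(0L, 2L)) {
    add("full", x, y, z)                                   # arms (16)
  }
  for (y in c(2L, 6L)) for (z in c(0L, 2L)) {
    add("full", 60L, y, z)                                 # head (4)
  }
  add("half", 0L, 2L, 4L); add("half", 0L, 6L, 4L)         # feet
  add("half", 60L, -4L, 0L); add("half", 60L, 12L, 0L)     # hands
  rows
}

mini_torso_placements <- function() {
  rot_z90 <- matrix(c(0L, -1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L), 3, byrow = TRUE)
  list(
    placement("p001", "full", c(0L, 0L, 0L), source_hole = 1L),
    placement("p002", "full", c(6L, 0L, 0L)),
    placement("p003", "full", c(0L, 4L, 0L)),
    placement("p004", "full", c(6L, 4L, 0L)),
    placement("p005", "full", c(0L, 0L, 2L), orientation = rot_z90),
    placement("p006", "half", c(6L, 0L, 2L), source_hole = 2L)
  )
}

#' Generate a canonical layout fixture
#'
#' Deterministic LDraw text for the bundled layouts:
#' \describe{
#'   \item{p70_stretcher}{The 70 kg configuration: 68 full + 4 half bricks
#'     arranged as a lying figure (legs, hips, torso, arms, head; half
#'     bricks as hands and feet), every brick with a rod source in hole 1.}
#'   \item{mini_torso}{A 6-brick smoke-test block (5 full + 1 half, one
#'     rotated brick, 2 rod sources).}
#'   \item{single_full}{One full brick at the origin, no source.}
#'   \item{single_half}{One half brick at the origin, no source.}
#' }
#'
#' @param name Fixture name.
#' @param registry A [brick_registry()].
#' @param catalog A [part_catalog()].
#' @param scale LDraw units per cm.
#' @return A single string of LDraw text.
#' @export
#' @examples
#' lay <- parse_ldraw(generate_canonical_layout("mini_torso"))
#' length(lay)  # 6
generate_canonical_layout <- function(name, registry = brick_registry(),
                                      catalog = part_catalog(),
                                      scale = default_config()$ldraw$scale) {
  placements <- switch(name,
    p70_stretcher = p70_placements(),
    mini_torso = mini_torso_placements(),
    single_full = list(placement("p001", "full")),
    single_half = list(placement("p001", "half")),
    bp_abort("bp_config_error", sprintf(
      "unknown fixture '%s'; available fixtures: %s", name,
      paste(canonical_fixture_names(), collapse = ", ")))
  )
  write_ldraw(brick_layout(placements), catalog = catalog, scale = scale,
              registry = registry, name = name)
}

#' Summarize a layout
#'
#' Brick counts by type, source counts by brick type, lattice extents,
#' solid mass at the configured polyethylene density, and collision status.
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @param config Configuration list.
#' @return Character vector of report lines; the first line is a compact
#'   one-liner (`"68 full, 4 half, 72 sources, extents 66x20x5"`).
#' @export
summarize_layout <- function(layout, registry = brick_registry(),
                             config = default_config()) {
  counts <- layout_counts(layout)
  src <- vapply(layout$placements, function(p) !is.na(p$source_hole), logical(1))
  types <- vapply(layout$placements, function(p) p$brick, character(1))
  nsrc <- sum(src)
  conflicts <- detect_collisions(layout, registry)
  ext <- if (length(conflicts) == 0L && length(layout$placements) > 0L) {
    build_segment_map(layout, registry)$extents
  } else c(0L, 0L, 0L)
  rho <- config$materials$polyethylene_density
  lines <- c(
    sprintf("%d full, %d half, %d sources, extents %dx%dx%d",
            counts["full"], counts["half"], nsrc, ext[1], ext[2], ext[3]),
    sprintf("bricks: %d full, %d half", counts["full"], counts["half"]),
    sprintf("rod sources: %d in full bricks, %d in half bricks",
            sum(src & types == "full"), sum(src & types == "half")),
    sprintf("lattice extents: %d x %d x %d cells (%s x %s x %s cm)",
            ext[1], ext[2], ext[3],
            fmt_num(ext[1] * lattice_unit(registry)),
            fmt_num(ext[2] * lattice_unit(registry)),
            fmt_num(ext[3] * lattice_unit(registry))),
    sprintf("solid mass at %s g/cm3: %s kg (drill holes ignored)",
            fmt_num(rho), fmt_num(layout_mass(layout, registry, rho))),
    if (length(conflicts) == 0L) "collisions: none"
    else sprintf("collisions: %d conflicting pair(s)", length(conflicts))
  )
  lines
}
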