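#' Custom part catalog
#'
#' Maps the package's LDraw part ids onto brick type and source-hole
#' assignment.  Each brick type has one source-free part and four one-source
#' parts (`_s1` .. `_s4`), so the one-source-per-brick rule is enforced by
#' the encoding itself.
#'
#' @return A data frame with columns `part_id`, `brick`, `source_hole`.
#' @export
part_catalog <- function() {
  grid <- expand.grid(brick = c("full", "half"), hole = c(NA, 1:4),
                      stringsAsFactors = FALSE)
  part_id <- ifelse(is.na(grid$hole),
                    sprintf("uph_%s.dat", grid$brick),
                    sprintf("uph_%s_s%d.dat", grid$brick, grid$hole))
  data.frame(part_id = part_id, brick = grid$brick,
             source_hole = as.integer(grid$hole), stringsAsFactors = FALSE)
}

#' Classify an LDraw part id
#'
#' @param part_id Part file name from a line-type-1 record.
#' @param catalog A [part_catalog()].
#' @return List with `brick` (type id) and `source_hole` (1-4 or `NA`).
#' @export
#' @examples
#' classify_part("uph_half_s1.dat")  # half brick, source in hole 1
classify_part <- function(part_id, catalog = part_catalog()) {
  i <- match(tolower(part_id), tolower(catalog$part_id))
  if (is.na(i)) {
    bp_abort("bp_parse_error",
             sprintf("unknown part id '%s' (not in the brick phantom part catalog)", part_id))
  }
  list(brick = catalog$brick[i], source_hole = catalog$source_hole[i])
}

part_for <- function(brick, source_hole, catalog = part_catalog()) {
  if (is.na(source_hole)) {
    i <- which(catalog$brick == brick & is.na(catalog$source_hole))
  } else {
    i <- which(catalog$brick == brick & !is.na(catalog$source_hole) &
               catalog$source_hole == source_hole)
  }
  if (length(i) != 1L) {
    bp_abort("bp_config_error",
             sprintf("no catalog part for brick '%s', source hole %s", brick, source_hole))
  }
  catalog$part_id[i]
}

# Change of basis between the LDraw frame (x right, y DOWN, z into screen)
# and the phantom frame (z = vertical stacking axis):
#   (x, y, z)_ldraw -> (x, z, -y)_phantom
ldraw_basis <- function() {
  matrix(c(1, 0, 0,
           0, 0, 1,
           0, -1, 0), nrow = 3, byrow = TRUE)
}

#' Convert an LDraw pose to a lattice placement pose
#'
#' Maps an LDraw position/rotation pair into the phantom frame, snaps the
#' position to the 2.75 cm lattice and the matrix to the nearest signed
#' permutation.  The LDraw part origin is the brick's local min corner.
#'
#' @param ref List with `pos` (3 floats, LDraw units) and `matrix` (3x3,
#'   row-major as read) and `part_id`; see [parse_ldraw()].
#' @param scale LDraw units per cm (default 25: 1 LDU = 0.4 mm).
#' @param registry A [brick_registry()].
#' @param catalog A [part_catalog()].
#' @return List with `index` (integer lattice cell) and `orientation`.
#' @export
convert_pose <- function(ref, scale = default_config()$ldraw$scale,
                         registry = brick_registry(), catalog = part_catalog()) {
  C <- ldraw_basis()
  m_ph <- C %*% ref$matrix %*% t(C)
  m_round <- round(m_ph)
  if (max(abs(m_ph - m_round)) > 0.01 || !is_orientation(m_round)) {
    bp_abort("bp_orientation_error", sprintf(
      "part '%s': rotation matrix does not snap to a proper 90-degree orientation",
      ref$part_id))
  }
  cls <- classify_part(ref$part_id, catalog)
  dims <- registry[[cls$brick]]$dims
  u <- lattice_unit(registry)
  pos_ph <- as.vector(C %*% ref$pos) / scale
  mc <- pos_ph + rot_box_min(m_round, dims)
  idx <- round(mc / u)
  resid <- max(abs(mc - idx * u))
  if (resid > 0.01) {
    bp_abort("bp_parse_error", sprintf(
      "part '%s': position is %.4g cm off the %.4g cm lattice (misaligned layout)",
      ref$part_id, resid, u))
  }
  list(index = as.integer(idx), orientation = m_round)
}

split_ldraw_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", text)
}

#' Parse an LDraw layout
#'
#' Reads line-type-1 sub-file references (`1 colour x y z a b c d e f g h i
#' part`) whose part id is in the catalog and converts each into a lattice
#' placement.  Comment/meta lines (type 0) and drawing primitives (types
#' 2-5) are ignored; ignored primitive lines are recorded in the `notes`
#' attribute of the result.  Parsing is insensitive to line endings and
#' repeated whitespace.  Multi-model (MPD) documents are rejected.
#'
#' @param text LDraw content: a single string or a character vector of lines.
#' @param catalog A [part_catalog()].
#' @param scale LDraw units per cm.
#' @param registry A [brick_registry()].
#' @return A [brick_layout()]; placement order follows file order and pids
#'   are `p001`, `p002`, ...
#' @export
parse_ldraw <- function(text, catalog = part_catalog(),
                        scale = default_config()$ldraw$scale,
                        registry = brick_registry()) {
  if (!is.numeric(scale) || scale <= 0) {
    bp_abort("bp_config_error", "ldraw scale must be a positive number")
  }
  lines <- split_ldraw_lines(text)
  nfile <- sum(grepl("^\\s*0\\s+FILE\\b", lines, ignore.case = TRUE))
  if (nfile > 1L) {
    bp_abort("bp_parse_error",
             "multi-model (MPD) documents are not supported; export a flat single-model .ldr file")
  }
  placements <- list()
  notes <- character(0)
  for (ln in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tokens) == 0L || tokens[1] == "") next
    type <- tokens[1]
    if (type == "0") next
    if (type %in% c("2", "3", "4", "5")) {
      notes <- c(notes, sprintf("line %d: ignored line type %s", ln, type))
      next
    }
    if (type != "1") {
      bp_abort("bp_parse_error", sprintf("line %d: unknown LDraw line type '%s'", ln, type))
    }
    if (length(tokens) < 15L) {
      bp_abort("bp_parse_error",
               sprintf("line %d: line-type-1 record needs 14 fields, found %d",
                       ln, length(tokens) - 1L))
    }
    nums <- suppressWarnings(as.numeric(tokens[2:14]))
    if (anyNA(nums)) {
      bp_abort("bp_parse_error",
               sprintf("line %d: malformed numeric field '%s'",
                       ln, tokens[2:14][which(is.na(nums))[1]]))
    }
    part_id <- paste(tokens[15:length(tokens)], collapse = " ")
    ref <- list(color = as.integer(nums[1]), pos = nums[2:4],
                matrix = matrix(nums[5:13], nrow = 3, byrow = TRUE),
                part_id = part_id)
    cls <- classify_part(part_id, catalog)
    pose <- convert_pose(ref, scale = scale, registry = registry, catalog = catalog)
    placements[[length(placements) + 1L]] <- placement(
      pid = sprintf("p%03d", length(placements) + 1L),
      brick = cls$brick, index = pose$index,
      orientation = pose$orientation, source_hole = cls$source_hole)
  }
  layout <- brick_layout(placements)
  attr(layout, "notes") <- notes
  layout
}

#' Read an LDraw layout file
#'
#' @param path Path to a `.ldr` file.
#' @inheritParams parse_ldraw
#' @return A [brick_layout()].
#' @export
read_ldraw <- function(path, catalog = part_catalog(),
                       scale = default_config()$ldraw$scale,
                       registry = brick_registry()) {
  if (!file.exists(path)) {
    bp_abort("bp_io_error", sprintf("LDraw file '%s' not found", path))
  }
  parse_ldraw(readLines(path, warn = FALSE), catalog = catalog,
              scale = scale, registry = registry)
}

fmt_ld <- function(x) {
  s <- sprintf("%.9f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  ifelse(s == "-0", "0", s)
}

#' Write a layout as LDraw text
#'
#' Inverse of [parse_ldraw()]: emits one line-type-1 record per placement
#' (colour 16, row-major rotation matrix) after a short type-0 header, so
#' that parsing the output reproduces the layout placement-for-placement.
#'
#' @param layout A [brick_layout()].
#' @param catalog A [part_catalog()].
#' @param scale LDraw units per cm.
#' @param registry A [brick_registry()].
#' @param name Model name written into the header.
#' @return A single string of LDraw text (LF line endings).
#' @export
write_ldraw <- function(layout, catalog = part_catalog(),
                        scale = default_config()$ldraw$scale,
                        registry = brick_registry(), name = "layout") {
  C <- ldraw_basis()
  u <- lattice_unit(registry)
  lines <- c(sprintf("0 brick phantom layout: %s", name),
             sprintf("0 Name: %s.ldr", name),
             "0 !LDRAW_ORG Unofficial_Model")
  for (p in layout$placements) {
    dims <- registry[[p$brick]]$dims
    pos_ph <- p$index * u - rot_box_min(p$orientation, dims)
    pos_ld <- as.vector(t(C) %*% pos_ph) * scale
    m_ld <- t(C) %*% p$orientation %*% C
    part <- part_for(p$brick, p$source_hole, catalog)
    lines <- c(lines, paste("1 16",
                            paste(fmt_ld(pos_ld), collapse = " "),
                            paste(fmt_ld(t(m_ld)), collapse = " "),
                            part))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
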