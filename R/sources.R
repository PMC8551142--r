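#' Locate the rod sources of a layout in world space
#'
#' One record per placement that carries a rod source: the world-frame base
#' point of the active section (on the brick front face), the world axis
#' direction, the rod radius and active length, and the per-type sampling
#' weight (brick thickness relative to the full brick, i.e. 1 for full
#' bricks and 0.5 for half bricks).
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @return A data frame with columns `pid`, `brick`, `hole`, `bx, by, bz`,
#'   `ax, ay, az`, `radius`, `active_length`, `weight`.
#' @export
collect_sources <- function(layout, registry = brick_registry()) {
  u <- lattice_unit(registry)
  rows <- list()
  for (p in layout$placements) {
    if (is.na(p$source_hole)) next
    spec <- registry[[p$brick]]
    src <- spec$holes[spec$holes$kind == "source", ]
    if (!(p$source_hole %in% src$id)) {
      bp_abort("bp_config_error",
               sprintf("placement '%s': source hole %d is not one of the %d source drill holes",
                       p$pid, p$source_hole, nrow(src)))
    }
    hr <- src[src$id == p$source_hole, ]
    R <- p$orientation
    p0 <- placement_origin(p, registry)
    base <- p0 + as.vector(R %*% c(hr$cx, hr$cy, hr$cz))
    axis <- as.vector(R %*% c(hr$ax, hr$ay, hr$az))
    rows[[length(rows) + 1L]] <- data.frame(
      pid = p$pid, brick = p$brick, hole = p$source_hole,
      bx = base[1], by = base[2], bz = base[3],
      ax = axis[1], ay = axis[2], az = axis[3],
      radius = spec$rod$radius, active_length = spec$rod$active_length,
      weight = spec$source_weight, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(pid = character(0), brick = character(0), hole = integer(0),
                      bx = numeric(0), by = numeric(0), bz = numeric(0),
                      ax = numeric(0), ay = numeric(0), az = numeric(0),
                      radius = numeric(0), active_length = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Normalized per-source sampling weights
#'
#' Every rod source in a full brick receives the same overall sampling
#' probability; a rod source in a half brick receives exactly half of it.
#' Weights are normalized to sum to one.
#'
#' @param records Source records from [collect_sources()].
#' @param registry A [brick_registry()] (kept for interface symmetry; the
#'   per-type weights are already attached to the records).
#' @return Named numeric vector of probabilities (names = placement ids).
#' @export
#' @examples
#' # one full + one half source -> 2/3 and 1/3
source_weights <- function(records, registry = brick_registry()) {
  if (nrow(records) == 0L) {
    bp_abort("bp_config_error", "no sources defined")
  }
  stats::setNames(records$weight / sum(records$weight), records$pid)
}

#' Split one rod source across its lattice segments
#'
#' The active section is distributed over the (2.75 cm)^3 segments it
#' traverses; each traversed segment's share is the active length contained
#' in that segment divided by the total active length, so sampling is
#' spatially uniform along the rod.  The rod cylinder must lie inside its
#' brick's occupied cells and within a single transverse lattice column.
#'
#' @param record A single row of [collect_sources()] output.
#' @param segment_map A [build_segment_map()] result.
#' @param registry A [brick_registry()].
#' @return A data frame with one row per traversed segment: global cell
#'   `ci, cj, ck`, segment `universe`, axial interval `t0, t1` (cm along the
#'   rod), `share`, and the rejection bounding box `x0, x1, y0, y1, z0, z1`
#'   clipped to that segment.
#' @export
segment_fractions <- function(record, segment_map, registry = brick_registry()) {
  u <- segment_map$unit
  base <- c(record$bx, record$by, record$bz)
  axis <- c(record$ax, record$ay, record$az)
  k <- which(abs(axis) > 0.5)
  if (length(k) != 1L || abs(abs(axis[k]) - 1) > 1e-9) {
    bp_abort("bp_geometry_error",
             sprintf("source '%s': rod axis is not aligned with a lattice axis", record$pid))
  }
  s <- sign(axis[k])
  L <- record$active_length
  r <- record$radius
  tol <- 1e-9

  perp <- setdiff(1:3, k)
  pcell <- floor(base[perp] / u + tol)
  for (d in 1:2) {
    clo <- pcell[d] * u
    if (base[perp[d]] - r < clo - 1e-6 || base[perp[d]] + r > clo + u + 1e-6) {
      bp_abort("bp_geometry_error", sprintf(
        "source '%s': rod cylinder straddles a lattice column boundary; source drill holes must lie within a single (2.75 cm)^2 column",
        record$pid))
    }
  }

  a0 <- base[k]
  a1 <- a0 + s * L
  lo <- min(a0, a1); hi <- max(a0, a1)
  b_from <- ceiling(lo / u - tol)
  b_to <- floor(hi / u + tol)
  bnd <- if (b_from <= b_to) u * (b_from:b_to) else numeric(0)
  bnd <- bnd[bnd > lo + tol & bnd < hi - tol]
  tcross <- sort((bnd - a0) / s)
  breaks <- c(0, tcross, L)

  segcells <- segment_map$cells
  rows <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    amid <- a0 + s * (t0 + t1) / 2
    cell <- integer(3)
    cell[k] <- floor(amid / u + tol)
    cell[perp] <- pcell
    hit <- which(segcells$ci == cell[1] & segcells$cj == cell[2] &
                 segcells$ck == cell[3])
    if (length(hit) != 1L || segcells$pid[hit] != record$pid) {
      bp_abort("bp_geometry_error", sprintf(
        "source '%s': rod active section extends outside its brick's lattice cells at cell (%d, %d, %d)",
        record$pid, cell[1], cell[2], cell[3]))
    }
    bb_lo <- numeric(3); bb_hi <- numeric(3)
    bb_lo[perp] <- base[perp] - r
    bb_hi[perp] <- base[perp] + r
    aa <- sort(c(a0 + s * t0, a0 + s * t1))
    bb_lo[k] <- aa[1]; bb_hi[k] <- aa[2]
    rows[[length(rows) + 1L]] <- data.frame(
      pid = record$pid, ci = cell[1], cj = cell[2], ck = cell[3],
      universe = segcells$universe[hit], t0 = t0, t1 = t1,
      share = (t1 - t0) / L,
      x0 = bb_lo[1], x1 = bb_hi[1], y0 = bb_lo[2], y1 = bb_hi[2],
      z0 = bb_lo[3], z1 = bb_hi[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  stopifnot(abs(sum(out$share) - 1) < 1e-12)
  out
}

# Assemble the flat per-entry table (one row per source x traversed segment)
# with final probabilities prob = source weight x segment share.
source_entries <- function(records, weights, fractions) {
  ord <- order(records$pid)
  entries <- list()
  for (i in ord) {
    fr <- fractions[[i]]
    fr$brick <- records$brick[i]
    fr$hole <- records$hole[i]
    fr$radius <- records$radius[i]
    fr$bx <- records$bx[i]; fr$by <- records$by[i]; fr$bz <- records$bz[i]
    fr$ax <- records$ax[i]; fr$ay <- records$ay[i]; fr$az <- records$az[i]
    fr$prob <- unname(weights[records$pid[i]]) * fr$share
    entries[[length(entries) + 1L]] <- fr
  }
  out <- do.call(rbind, entries)
  if (abs(sum(out$prob) - 1) > 1e-12) {
    bp_abort("bp_geometry_error", "source probabilities do not normalize to 1")
  }
  out
}

#' Build the full source sampling distribution of a layout
#'
#' Combines [collect_sources()], [source_weights()] and
#' [segment_fractions()] into the ordered per-entry distribution used both
#' by the SDEF emitter and by the sampling oracle.
#'
#' @param layout A [brick_layout()].
#' @param registry A [brick_registry()].
#' @param plan A [numbering_plan()].
#' @param segment_map Optional precomputed [build_segment_map()] result.
#' @return `NULL` when the layout has no sources; otherwise an object of
#'   class `source_distribution`: list with `records`, `weights`,
#'   `fractions` (list parallel to the records) and `entries` (data frame,
#'   probabilities summing to 1 within 1e-12).
#' @export
build_source_distribution <- function(layout, registry = brick_registry(),
                                      plan = numbering_plan(),
                                      segment_map = NULL) {
  records <- collect_sources(layout, registry)
  if (nrow(records) == 0L) return(NULL)
  if (is.null(segment_map)) {
    segment_map <- build_segment_map(layout, registry, plan)
  }
  weights <- source_weights(records, registry)
  fractions <- lapply(seq_len(nrow(records)), function(i)
    segment_fractions(records[i, ], segment_map, registry))
  entries <- source_entries(records, weights, fractions)
  structure(list(records = records, weights = weights,
                 fractions = fractions, entries = entries),
            class = "source_distribution")
}

#' @export
print.source_distribution <- function(x, ...) {
  cat(sprintf("<source_distribution> %d rod sources, %d sampling entries, total probability %.15g\n",
              nrow(x$records), nrow(x$entries), sum(x$entries$prob)))
  invisible(x)
}

#' Emit the SDEF source definition cards
#'
#' Writes the volumetric source block: an SDEF card with a discrete cell
#' distribution (SI L of path-form cell references `rod < segment <
#' lattice[i j k] < container`, SP probabilities = source weight x segment
#' share) and, per entry, dependent X/Y/Z distributions sampling uniformly
#' over the segment-clipped bounding box of the rod cylinder with rejection
#' against the rod active cell.  Entry order is deterministic (placement id,
#' then segment).
#'
#' @param records Source records from [collect_sources()].
#' @param weights Normalized weights from [source_weights()].
#' @param fractions List of [segment_fractions()] results, parallel to
#'   `records`.
#' @param plan A [numbering_plan()].
#' @param config Configuration list (placeholder photon energy).
#' @return List of data cards.
#' @export
emit_sdef <- function(records, weights, fractions, plan = numbering_plan(),
                      config = default_config()) {
  entries <- source_entries(records, weights, fractions)
  n <- nrow(entries)
  if (3L * n + 4L > 999L) {
    bp_abort("bp_config_error", sprintf(
      "%d source sampling entries need more than the 999 available distribution numbers", n))
  }
  rod_cell <- vapply(seq_len(n), function(i)
    as.integer(plan$template_cell[[entries$brick[i]]] + 4L + entries$hole[i]),
    integer(1))
  seg_cell <- plan$segment_cell_base + entries$universe
  paths <- sprintf("(%d<%d<%d[%d %d %d]<%d)", rod_cell, seg_cell,
                   plan$lattice_cell, entries$ci, entries$cj, entries$ck,
                   plan$container_cell)
  cards <- list()
  add <- function(cd) cards[[length(cards) + 1L]] <<- cd
  add(mcnp_comment("data", sprintf(
    "sdef: %d rod sources over %d lattice segments, cell rejection sampling",
    nrow(records), n)))
  add(mcnp_card("data",
                sprintf("sdef par=2 erg=%s cel=d1 x=fcel=d2 y=fcel=d3 z=fcel=d4 $ energy placeholder",
                        fmt_num(config$mcnp$source_energy_mev))))
  add(mcnp_card("data", paste("si1 L", paste(paths, collapse = " ")),
                refs = list(cell = unique(c(rod_cell, seg_cell,
                                            plan$lattice_cell,
                                            plan$container_cell)))))
  add(mcnp_card("data", paste("sp1", paste(fmt_prob(entries$prob), collapse = " "))))
  ids <- function(axis) 3L * seq_len(n) + 1L + axis  # axis 1..3 -> x,y,z
  add(mcnp_card("data", paste("ds2 s", paste(ids(1L), collapse = " "))))
  add(mcnp_card("data", paste("ds3 s", paste(ids(2L), collapse = " "))))
  add(mcnp_card("data", paste("ds4 s", paste(ids(3L), collapse = " "))))
  lo <- as.matrix(entries[, c("x0", "y0", "z0")])
  hi <- as.matrix(entries[, c("x1", "y1", "z1")])
  for (i in seq_len(n)) {
    for (axis in 1:3) {
      add(mcnp_card("data", sprintf("si%d h %s %s", 3L * i + 1L + axis,
                                    fmt_num(lo[i, axis]), fmt_num(hi[i, axis]))))
      add(mcnp_card("data", sprintf("sp%d d 0 1", 3L * i + 1L + axis)))
    }
  }
  cards
}
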