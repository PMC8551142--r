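#' Deterministic id numbering plan
#'
#' Allocates surface, cell, universe, transform and material ids for the
#' generated deck.  The plan is a pure function of the configuration, so the
#' same layout always yields the same deck.  Defaults: surfaces from 1000
#' (30-id block per brick type, shared surfaces from 1090), template cells
#' from 100 (50-id block per type), segment-universe cells at 5000 +
#' universe, segment universes from 200 (full) / 400 (half), lattice cell
#' 10, world/buffer/graveyard cells 2/4/3, background-universe cell 50, TR
#' cards from 900.
#'
#' @param config Configuration list, see [default_config()].
#' @return A list of id bases and per-type id tables.
#' @export
numbering_plan <- function(config = default_config()) {
  nb <- lapply(config$numbering, function(x) as.integer(round(x)))
  types <- names(config$bricks)
  surfaces <- list()
  template_cell <- list()
  segment_universe <- list()
  template_universe <- list()
  for (i in seq_along(types)) {
    t <- types[i]
    sb <- nb$surface_base + (i - 1L) * 30L
    surfaces[[t]] <- list(box = sb, holes = sb + 1:4, rods = sb + 5:8,
                          plugs = sb + 9:12, conns = sb + 13:16)
    template_cell[[t]] <- nb$template_cell_base + (i - 1L) * 50L
    segment_universe[[t]] <- nb[[paste0("segment_universe_", t)]]
    template_universe[[t]] <- nb[[paste0("template_universe_", t)]]
    if (is.null(segment_universe[[t]]) || is.null(template_universe[[t]])) {
      bp_abort("bp_config_error",
               sprintf("numbering plan lacks universe bases for brick type '%s'", t))
    }
  }
  shared <- nb$surface_base + 90L
  list(types = types,
       surfaces = surfaces,
       surface_element = shared,
       surface_lattice_box = shared + 1L,
       surface_world = shared + 2L,
       surface_background = shared + 3L,
       template_cell = template_cell,
       segment_cell_base = nb$segment_cell_base,
       template_universe = template_universe,
       segment_universe = segment_universe,
       lattice_universe = nb$lattice_universe,
       background_universe = nb$background_universe,
       lattice_cell = nb$lattice_cell,
       container_cell = nb$container_cell,
       graveyard_cell = nb$graveyard_cell,
       buffer_cell = nb$buffer_cell,
       background_cell = nb$background_cell,
       transform_base = nb$transform_base,
       material_polyethylene = nb$material_polyethylene,
       material_air = nb$material_air)
}

rcc_card <- function(id, base, axis, radius) {
  mcnp_card("surface",
            paste(id, "rcc", paste(fmt_num(base), collapse = " "),
                  paste(fmt_num(axis), collapse = " "), fmt_num(radius)),
            defines = list(surface = id))
}

#' Emit the per-brick template and segment universes
#'
#' For each brick type this writes the analytical brick geometry (RPP body;
#' RCC source drill holes, rod active sections and optional plugs; RCC
#' connector blind holes) into one template universe, then clips that
#' template into 48 (full) or 24 (half) unit-cube segment universes via
#' universe/fill with a per-segment translation.  Rod active sections are
#' air-filled cells that exist as sampling targets for the SDEF cell
#' rejection, so the geometry is identical whether or not a given brick
#' carries a source.
#'
#' @param registry A [brick_registry()].
#' @param config Configuration list.
#' @param plan A [numbering_plan()].
#' @return List of cards (surface and cell blocks).
#' @export
emit_template_universes <- function(registry, config, plan = numbering_plan(config)) {
  u <- lattice_unit(registry)
  rho_poly <- config$materials$polyethylene_density
  rho_air <- config$materials$air_density
  m_poly <- plan$material_polyethylene
  m_air <- plan$material_air
  cards <- list()
  add <- function(cd) cards[[length(cards) + 1L]] <<- cd

  h <- u / 2
  add(mcnp_card("surface",
                sprintf("%d rpp %s %s %s %s %s %s", plan$surface_element,
                        fmt_num(-h), fmt_num(h), fmt_num(-h), fmt_num(h),
                        fmt_num(-h), fmt_num(h)),
                defines = list(surface = plan$surface_element)))

  for (t in plan$types) {
    spec <- registry[[t]]
    sid <- plan$surfaces[[t]]
    tc <- plan$template_cell[[t]]
    tu <- plan$template_universe[[t]]
    dims <- spec$dims
    src <- spec$holes[spec$holes$kind == "source", ]
    conn <- spec$holes[spec$holes$kind == "connector", ]
    rod <- spec$rod
    has_plug <- rod$plug_length > 0

    add(mcnp_comment("cell", sprintf("%s brick template, universe %d", t, tu)))
    add(mcnp_card("surface",
                  sprintf("%d rpp 0 %s 0 %s 0 %s", sid$box,
                          fmt_num(dims[1]), fmt_num(dims[2]), fmt_num(dims[3])),
                  defines = list(surface = sid$box)))
    for (j in 1:4) {
      hr <- src[j, ]
      ax <- c(hr$ax, hr$ay, hr$az)
      add(rcc_card(sid$holes[j], c(hr$cx, hr$cy, hr$cz), ax * hr$depth, hr$radius))
      add(rcc_card(sid$rods[j], c(hr$cx, hr$cy, hr$cz), ax * rod$active_length,
                   rod$radius))
      if (has_plug) {
        add(rcc_card(sid$plugs[j], c(hr$cx, hr$cy, hr$cz) + ax * rod$active_length,
                     ax * rod$plug_length, rod$radius))
      }
    }
    for (j in seq_len(nrow(conn))) {
      cr <- conn[j, ]
      add(rcc_card(sid$conns[j], c(cr$cx, cr$cy, cr$cz),
                   c(cr$ax, cr$ay, cr$az) * cr$depth, cr$radius))
    }

    void_surfs <- c(sid$holes, sid$conns)
    add(mcnp_card("cell",
                  sprintf("%d %d %s -%d %s u=%d imp:p=1", tc, m_poly,
                          fmt_num(-rho_poly), sid$box,
                          paste(void_surfs, collapse = " "), tu),
                  defines = list(cell = tc, universe = tu),
                  refs = list(surface = c(sid$box, void_surfs),
                              material = m_poly)))
    for (j in 1:4) {
      excl <- sid$rods[j]
      if (has_plug) excl <- c(excl, sid$plugs[j])
      add(mcnp_card("cell",
                    sprintf("%d %d %s -%d %s u=%d imp:p=1 $ source hole %d",
                            tc + j, m_air, fmt_num(-rho_air), sid$holes[j],
                            paste(excl, collapse = " "), tu, j),
                    defines = list(cell = tc + j),
                    refs = list(surface = c(sid$holes[j], excl), material = m_air)))
    }
    for (j in 1:4) {
      add(mcnp_card("cell",
                    sprintf("%d %d %s -%d u=%d imp:p=1 $ rod active, hole %d",
                            tc + 4L + j, m_air, fmt_num(-rho_air), sid$rods[j],
                            tu, j),
                    defines = list(cell = tc + 4L + j),
                    refs = list(surface = sid$rods[j], material = m_air)))
    }
    if (has_plug) {
      for (j in 1:4) {
        add(mcnp_card("cell",
                      sprintf("%d 0 -%d u=%d imp:p=1 $ rod plug, hole %d",
                              tc + 8L + j, sid$plugs[j], tu, j),
                      defines = list(cell = tc + 8L + j),
                      refs = list(surface = sid$plugs[j])))
      }
    }
    for (j in seq_len(nrow(conn))) {
      add(mcnp_card("cell",
                    sprintf("%d %d %s -%d u=%d imp:p=1 $ connector hole",
                            tc + 12L + j, m_air, fmt_num(-rho_air),
                            sid$conns[j], tu),
                    defines = list(cell = tc + 12L + j),
                    refs = list(surface = sid$conns[j], material = m_air)))
    }
    add(mcnp_card("cell",
                  sprintf("%d %d %s %d u=%d imp:p=1 $ air outside the brick box",
                          tc + 17L, m_air, fmt_num(-rho_air), sid$box, tu),
                  defines = list(cell = tc + 17L),
                  refs = list(surface = sid$box, material = m_air)))

    # one (2.75 cm)^3 segment universe per template sub-volume
    add(mcnp_comment("cell",
                     sprintf("%s brick segment universes %d..%d", t,
                             plan$segment_universe[[t]],
                             plan$segment_universe[[t]] + prod(spec$seg) - 1L)))
    sc <- spec$seg
    for (lc in 0:(sc[3] - 1L)) for (lb in 0:(sc[2] - 1L)) for (la in 0:(sc[1] - 1L)) {
      ord <- la + sc[1] * lb + sc[1] * sc[2] * lc
      su <- plan$segment_universe[[t]] + ord
      cid <- plan$segment_cell_base + su
      ctr <- (c(la, lb, lc) + 0.5) * u
      add(mcnp_card("cell",
                    sprintf("%d 0 -%d fill=%d (%s) u=%d imp:p=1",
                            cid, plan$surface_element, tu,
                            paste(fmt_num(-ctr), collapse = " "), su),
                    defines = list(cell = cid, universe = su),
                    refs = list(surface = plan$surface_element, universe = tu)))
    }
  }
  cards
}

#' Emit the fully-specified lattice
#'
#' Writes one LAT=1 lattice cell whose FILL array lists, for every lattice
#' element of the layout bounding box, either the segment universe occupying
#' that cell (with a shared TR reference when the placement is rotated) or
#' the background air universe.  Entry order is i-fastest, then j, then k.
#' At most 23 TR cards are emitted (one per distinct non-identity
#' orientation; the identity is written bare).
#'
#' @param segment_map A [build_segment_map()] result.
#' @param plan A [numbering_plan()].
#' @param air_density Air density (g/cm3) for the background universe cell.
#' @return List of cards (the lattice cell, background universe cell, their
#'   surfaces and the TR cards).
#' @export
emit_lattice <- function(segment_map, plan = numbering_plan(),
                         air_density = default_config()$materials$air_density) {
  ext <- segment_map$extents
  if (any(ext == 0L)) {
    bp_abort("bp_geometry_error", "segment map is empty; nothing to place on the lattice")
  }
  u <- segment_map$unit
  org <- segment_map$origin
  segs <- segment_map$cells

  okeys <- sort(unique(segs$okey[segs$okey != orientation_key(diag(3))]))
  tr_ids <- if (length(okeys)) stats::setNames(plan$transform_base + seq_along(okeys) - 1L, okeys)
            else integer(0)

  nx <- ext[1]; ny <- ext[2]; nz <- ext[3]
  tokens <- rep(as.character(plan$background_universe), nx * ny * nz)
  fills <- rep(as.integer(plan$background_universe), nx * ny * nz)
  pos <- (segs$ci - org[1]) + nx * (segs$cj - org[2]) + nx * ny * (segs$ck - org[3]) + 1L
  rot <- segs$okey != orientation_key(diag(3))
  tokens[pos] <- ifelse(rot,
                        sprintf("%d(%d)", segs$universe, tr_ids[segs$okey]),
                        as.character(segs$universe))
  fills[pos] <- segs$universe

  cards <- list()
  add <- function(cd) cards[[length(cards) + 1L]] <<- cd
  add(mcnp_comment("cell", "fully-specified lattice of 2.75 cm segments"))
  lat_text <- paste(plan$lattice_cell, "0",
                    sprintf("-%d", plan$surface_element),
                    sprintf("lat=1 u=%d imp:p=1", plan$lattice_universe),
                    sprintf("fill=%d:%d %d:%d %d:%d",
                            org[1], org[1] + nx - 1L,
                            org[2], org[2] + ny - 1L,
                            org[3], org[3] + nz - 1L),
                    paste(tokens, collapse = " "))
  add(mcnp_card("cell", lat_text,
                defines = list(cell = plan$lattice_cell,
                               universe = plan$lattice_universe,
                               fill_n = nx * ny * nz,
                               fill_entries = fills),
                refs = list(surface = plan$surface_element,
                            universe = sort(unique(fills)),
                            transform = unname(tr_ids))))
  add(mcnp_card("cell",
                sprintf("%d %d %s -%d u=%d imp:p=1 $ background air",
                        plan$background_cell, plan$material_air,
                        fmt_num(-air_density), plan$surface_background,
                        plan$background_universe),
                defines = list(cell = plan$background_cell,
                               universe = plan$background_universe),
                refs = list(surface = plan$surface_background,
                            material = plan$material_air)))
  add(mcnp_card("surface",
                sprintf("%d so 10000", plan$surface_background),
                defines = list(surface = plan$surface_background)))
  lo <- org * u
  hi <- (org + ext) * u
  add(mcnp_card("surface",
                sprintf("%d rpp %s", plan$surface_lattice_box,
                        paste(fmt_num(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])),
                              collapse = " ")),
                defines = list(surface = plan$surface_lattice_box)))
  for (k in okeys) {
    m <- matrix(as.integer(strsplit(k, " ")[[1]]), 3, 3)
    add(mcnp_card("data",
                  sprintf("tr%d 0 0 0 %s", tr_ids[k],
                          paste(fmt_num(as.vector(t(m))), collapse = " ")),
                  defines = list(transform = unname(tr_ids[k]))))
  }
  cards
}

#' Build the complete MCNP deck for a layout
#'
#' Assembles title, cell, surface and data blocks: brick template and
#' segment universes, the fully-specified lattice, the world (lattice
#' container, air buffer, graveyard), materials (high-density polyethylene
#' as CH2 and air), MODE P, the SDEF source block and an NPS placeholder.
#' The result is a pure function of its inputs and passes the reference-
#' closure linter.
#'
#' @param layout A collision-free [brick_layout()].
#' @param registry A [brick_registry()].
#' @param config Configuration list.
#' @return An [mcnp_deck()].
#' @export
build_deck <- function(layout, registry = brick_registry(),
                       config = default_config()) {
  plan <- numbering_plan(config)
  smap <- build_segment_map(layout, registry, plan)
  if (any(smap$extents == 0L)) {
    bp_abort("bp_geometry_error", "layout is empty; nothing to write")
  }
  u <- smap$unit
  rho_air <- config$materials$air_density
  margin <- config$mcnp$world_margin_cm
  cards <- list()
  add <- function(cds) {
    if (inherits(cds, "mcnp_card")) cds <- list(cds)
    for (cd in cds) cards[[length(cards) + 1L]] <<- cd
  }

  lo <- smap$origin * u - margin
  hi <- (smap$origin + smap$extents) * u + margin
  add(mcnp_comment("cell", "world"))
  add(mcnp_card("cell",
                sprintf("%d 0 -%d fill=%d (%s %s %s) imp:p=1 $ lattice container",
                        plan$container_cell, plan$surface_lattice_box,
                        plan$lattice_universe,
                        fmt_num(u / 2), fmt_num(u / 2), fmt_num(u / 2)),
                defines = list(cell = plan$container_cell),
                refs = list(surface = plan$surface_lattice_box,
                            universe = plan$lattice_universe)))
  add(mcnp_card("cell",
                sprintf("%d %d %s %d -%d imp:p=1 $ air buffer",
                        plan$buffer_cell, plan$material_air, fmt_num(-rho_air),
                        plan$surface_lattice_box, plan$surface_world),
                defines = list(cell = plan$buffer_cell),
                refs = list(surface = c(plan$surface_lattice_box,
                                        plan$surface_world),
                            material = plan$material_air)))
  add(mcnp_card("cell",
                sprintf("%d 0 %d imp:p=0 $ graveyard",
                        plan$graveyard_cell, plan$surface_world),
                defines = list(cell = plan$graveyard_cell),
                refs = list(surface = plan$surface_world)))
  add(mcnp_card("surface",
                sprintf("%d rpp %s", plan$surface_world,
                        paste(fmt_num(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3])),
                              collapse = " ")),
                defines = list(surface = plan$surface_world)))

  add(emit_lattice(smap, plan, air_density = rho_air))
  add(emit_template_universes(registry, config, plan))

  add(mcnp_comment("data", "data block"))
  add(mcnp_card("data", "mode p"))
  add(mcnp_card("data",
                sprintf("m%d 1001 2 6000 1 $ high-density polyethylene, %s g/cm3",
                        plan$material_polyethylene,
                        fmt_num(config$materials$polyethylene_density)),
                defines = list(material = plan$material_polyethylene)))
  add(mcnp_card("data",
                sprintf("m%d 7014 -0.755 8016 -0.232 18000 -0.013 $ air",
                        plan$material_air),
                defines = list(material = plan$material_air)))

  dist <- build_source_distribution(layout, registry, plan, segment_map = smap)
  if (is.null(dist)) {
    add(mcnp_comment("data",
                     "no rod sources in this layout; add an sdef block before running"))
  } else {
    add(emit_sdef(dist$records, dist$weights, dist$fractions, plan, config))
  }
  add(mcnp_card("data", sprintf("nps %s $ adjust the number of histories",
                                fmt_num(config$mcnp$nps))))

  counts <- layout_counts(layout)
  title <- sprintf("brick phantom: %d full + %d half bricks on a %s cm lattice",
                   counts["full"], counts["half"], fmt_num(u))
  deck <- mcnp_deck(title, cards)
  issues <- lint_deck(deck)
  if (length(issues) > 0L) {
    bp_abort("bp_geometry_error",
             paste("generated deck failed the internal linter:",
                   paste(issues, collapse = "; ")))
  }
  deck
}

#' Serialize a layout straight to MCNP input text
#'
#' Convenience wrapper: [build_deck()] followed by [serialize_deck()].
#' Byte-identical output for identical inputs.
#'
#' @inheritParams build_deck
#' @return A single string holding the MCNP input deck.
#' @export
emit_deck <- function(layout, registry = brick_registry(),
                      config = default_config()) {
  serialize_deck(build_deck(layout, registry, config))
}
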