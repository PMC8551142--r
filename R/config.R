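#' Default configuration
#'
#' All tunable dimensions, materials, conventions and numbering bases used by
#' the generator.  Every value can be overridden from a YAML file via
#' [load_config()].  Lengths are centimetres, densities g/cm3.
#'
#' Key groups:
#' \describe{
#'   \item{bricks}{Outer dimensions of the full and half brick.  The full
#'     brick is 16.5 x 11 x 5.5 cm and the half brick 16.5 x 11 x 2.75 cm, so
#'     their edges stand in ratios 6:4:2 and 6:4:1 of the 2.75 cm lattice
#'     unit.}
#'   \item{holes}{Source drill holes (four per brick, perpendicular to the
#'     16.5 x 11 cm front face) and connector blind holes (one per side
#'     face).  `depth: NA` means "the brick thickness".  The transverse
#'     offsets `dx`, `dy` are measured from the front-face centre; the
#'     defaults place each hole at the centre of a lattice column.}
#'   \item{rod}{Rod-source dimensions; the active section starts flush with
#'     the front face.  `active_length: NA` derives thickness - plug_length.}
#'   \item{materials}{High-density polyethylene and air mass densities.}
#'   \item{ldraw}{LDraw units per centimetre (25 = the standard 0.4 mm LDU).}
#'   \item{mcnp}{Deck skeleton parameters: placeholder photon energy (MeV),
#'     world margin around the lattice, NPS placeholder.}
#'   \item{sampling}{Default seed for the sampling oracle.}
#'   \item{numbering}{Deterministic id bases for surfaces, cells, universes,
#'     transforms and materials.}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    bricks = list(
      full = list(dims = c(16.5, 11, 5.5)),
      half = list(dims = c(16.5, 11, 2.75))
    ),
    holes = list(
      source = list(radius = 0.4, depth = NA, dx = 4.125, dy = 4.125),
      connector = list(radius = 0.3, depth = 1.0)
    ),
    rod = list(radius = 0.35, active_length = NA, plug_length = 0),
    materials = list(polyethylene_density = 0.95, air_density = 1.205e-3),
    ldraw = list(scale = 25),
    mcnp = list(source_energy_mev = 0.662, world_margin_cm = 50, nps = 1e6),
    sampling = list(seed = 20210828),
    numbering = list(
      surface_base = 1000,
      template_cell_base = 100,
      segment_cell_base = 5000,
      template_universe_full = 20,
      template_universe_half = 30,
      segment_universe_full = 200,
      segment_universe_half = 400,
      lattice_universe = 1,
      background_universe = 5,
      lattice_cell = 10,
      container_cell = 2,
      graveyard_cell = 3,
      buffer_cell = 4,
      background_cell = 50,
      transform_base = 900,
      material_polyethylene = 1,
      material_air = 2
    )
  )
}

# Recursive merge of an override list onto the defaults.  Unknown keys are a
# configuration error (no silent typos).
merge_config <- function(base, override, path = character()) {
  if (length(override) == 0L) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    bp_abort("bp_config_error",
             sprintf("configuration group '%s' must contain named keys",
                     paste(path, collapse = ".")))
  }
  for (nm in nms) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base)) {
      bp_abort("bp_config_error", sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(base[[nm]])) {
      if (!is.list(override[[nm]])) {
        bp_abort("bp_config_error",
                 sprintf("configuration key '%s' must be a group", full))
      }
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else {
      val <- override[[nm]]
      if (is.list(val)) val <- unlist(val)
      base[[nm]] <- val
    }
  }
  base
}

check_num <- function(x, key, n = 1L, positive = FALSE, nonneg = FALSE,
                      na_ok = FALSE) {
  if (na_ok && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != n || anyNA(x) || any(!is.finite(x))) {
    bp_abort("bp_config_error",
             sprintf("configuration key '%s' must be %d finite numeric value(s)",
                     key, n))
  }
  if (positive && any(x <= 0)) {
    bp_abort("bp_config_error", sprintf("configuration key '%s' must be > 0", key))
  }
  if (nonneg && any(x < 0)) {
    bp_abort("bp_config_error", sprintf("configuration key '%s' must be >= 0", key))
  }
  invisible(x)
}

validate_config <- function(config) {
  check_num(config$bricks$full$dims, "bricks.full.dims", 3L, positive = TRUE)
  check_num(config$bricks$half$dims, "bricks.half.dims", 3L, positive = TRUE)
  check_num(config$holes$source$radius, "holes.source.radius", positive = TRUE)
  check_num(config$holes$source$depth, "holes.source.depth", positive = TRUE, na_ok = TRUE)
  check_num(config$holes$source$dx, "holes.source.dx", positive = TRUE)
  check_num(config$holes$source$dy, "holes.source.dy", positive = TRUE)
  check_num(config$holes$connector$radius, "holes.connector.radius", positive = TRUE)
  check_num(config$holes$connector$depth, "holes.connector.depth", positive = TRUE)
  check_num(config$rod$radius, "rod.radius", positive = TRUE)
  check_num(config$rod$active_length, "rod.active_length", positive = TRUE, na_ok = TRUE)
  check_num(config$rod$plug_length, "rod.plug_length", nonneg = TRUE)
  check_num(config$materials$polyethylene_density, "materials.polyethylene_density",
            positive = TRUE)
  check_num(config$materials$air_density, "materials.air_density", positive = TRUE)
  check_num(config$ldraw$scale, "ldraw.scale", positive = TRUE)
  check_num(config$mcnp$source_energy_mev, "mcnp.source_energy_mev", positive = TRUE)
  check_num(config$mcnp$world_margin_cm, "mcnp.world_margin_cm", positive = TRUE)
  check_num(config$mcnp$nps, "mcnp.nps", positive = TRUE)
  if (config$rod$radius > config$holes$source$radius) {
    bp_abort("bp_config_error",
             "rod.radius must not exceed holes.source.radius (rod must fit the drill hole)")
  }
  for (nm in names(config$numbering)) {
    check_num(config$numbering[[nm]], paste0("numbering.", nm), nonneg = TRUE)
  }
  invisible(config)
}

#' Load and validate a configuration
#'
#' Merges a YAML configuration file onto [default_config()].  Unknown keys
#' and out-of-range values raise a configuration error, so typos never pass
#' silently.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet If `FALSE`, echo the effective configuration to stderr.
#' @return The validated configuration list.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      bp_abort("bp_io_error", sprintf("configuration file '%s' not found", path))
    }
    override <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) bp_abort("bp_config_error",
                                   sprintf("cannot read YAML '%s': %s", path,
                                           conditionMessage(e)))
    )
    if (!is.null(override)) config <- merge_config(config, override)
  }
  config <- validate_config(config)
  if (!quiet) {
    message("effective configuration:")
    message(yaml::as.yaml(config))
  }
  config
}
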