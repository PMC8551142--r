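#' Build an MCNP deck from an LDraw layout file
#'
#' End-to-end pipeline: read and parse the LDraw file, check for
#' collisions, assemble and lint the MCNP deck, and write the deck (and
#' optionally a layout summary) with LF line endings.  All failures raise
#' typed conditions (`bp_parse_error`, `bp_collision_error`,
#' `bp_orientation_error`, `bp_config_error`, `bp_io_error`), which the
#' command-line wrapper maps onto distinct exit codes.
#'
#' @param input Path to the LDraw layout file.
#' @param output Path for the MCNP deck.
#' @param summary Optional path for the text summary report.
#' @param config_path Optional YAML configuration file.
#' @param scale Override for the LDraw scale (LDU per cm).
#' @return Invisibly, a list with the parsed `layout`, the `deck` object and
#'   the `summary` lines.
#' @export
run_build <- function(input, output, summary = NULL, config_path = NULL,
                      scale = NULL) {
  config <- load_config(config_path)
  if (!is.null(scale)) {
    check_num(scale, "ldraw.scale", positive = TRUE)
    config$ldraw$scale <- scale
  }
  registry <- brick_registry(config)
  catalog <- part_catalog()
  layout <- read_ldraw(input, catalog = catalog, scale = config$ldraw$scale,
                       registry = registry)
  conflicts <- detect_collisions(layout, registry)
  if (length(conflicts) > 0L) {
    desc <- vapply(conflicts, function(cf)
      sprintf("%s/%s (%d cells)", cf$a, cf$b, nrow(cf$cells)), character(1))
    bp_abort("bp_collision_error",
             sprintf("layout has overlapping bricks: %s", paste(desc, collapse = "; ")),
             conflicts = conflicts)
  }
  deck <- build_deck(layout, registry, config)
  write_text(serialize_deck(deck), output)
  lines <- summarize_layout(layout, registry, config)
  if (!is.null(summary)) write_text(paste0(paste(lines, collapse = "\n"), "\n"), summary)
  invisible(list(layout = layout, deck = deck, summary = lines))
}

write_text <- function(text, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    bp_abort("bp_io_error", sprintf("output directory '%s' does not exist", dir))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(path)
}

# Exit-code mapping used by the command-line wrapper (inst/cli).
bp_exit_code <- function(cond) {
  classes <- class(cond)
  if ("bp_parse_error" %in% classes) return(2L)
  if ("bp_collision_error" %in% classes) return(3L)
  if ("bp_orientation_error" %in% classes) return(4L)
  if ("bp_config_error" %in% classes) return(5L)
  if ("bp_io_error" %in% classes) return(6L)
  if ("bp_geometry_error" %in% classes) return(7L)
  1L
}

#' Run a CLI command programmatically
#'
#' Backend of the `inst/cli/brickphantom.R` script.  Commands:
#' \describe{
#'   \item{build}{LDraw file to MCNP deck (+ summary).}
#'   \item{check}{Parse and collision-check only.}
#'   \item{summarize}{Parse and print the layout summary.}
#'   \item{fixture}{Emit a canonical layout (see
#'     [generate_canonical_layout()]).}
#' }
#'
#' @param command One of `build`, `check`, `summarize`, `fixture`.
#' @param input Input LDraw path (or fixture name for `fixture`).
#' @param output Output path where the command writes a file.
#' @param summary Optional summary path for `build`.
#' @param config_path Optional YAML configuration file.
#' @param scale Optional LDraw scale override.
#' @return A list with `status` (0 on success, a category-specific code
#'   otherwise) and `message`.
#' @export
run_cli <- function(command, input = NULL, output = NULL, summary = NULL,
                    config_path = NULL, scale = NULL) {
  result <- tryCatch({
    switch(command,
      build = {
        if (is.null(input) || is.null(output)) {
          bp_abort("bp_io_error", "build requires an input LDraw file and an output path")
        }
        res <- run_build(input, output, summary = summary,
                         config_path = config_path, scale = scale)
        list(status = 0L, message = sprintf("deck written to %s", output),
             data = res)
      },
      check = ,
      summarize = {
        if (is.null(input)) bp_abort("bp_io_error", "an input LDraw file is required")
        config <- load_config(config_path)
        if (!is.null(scale)) config$ldraw$scale <- scale
        registry <- brick_registry(config)
        layout <- read_ldraw(input, scale = config$ldraw$scale, registry = registry)
        conflicts <- detect_collisions(layout, registry)
        if (length(conflicts) > 0L) {
          desc <- vapply(conflicts, function(cf)
            sprintf("%s/%s (%d cells)", cf$a, cf$b, nrow(cf$cells)), character(1))
          bp_abort("bp_collision_error",
                   sprintf("layout has overlapping bricks: %s",
                           paste(desc, collapse = "; ")))
        }
        msg <- if (command == "check") "layout parses cleanly, no collisions"
               else paste(summarize_layout(layout, registry, config), collapse = "\n")
        list(status = 0L, message = msg)
      },
      fixture = {
        if (is.null(input)) {
          bp_abort("bp_config_error", sprintf(
            "fixture requires a name; available: %s",
            paste(canonical_fixture_names(), collapse = ", ")))
        }
        text <- generate_canonical_layout(input)
        if (!is.null(output)) write_text(text, output)
        list(status = 0L,
             message = if (is.null(output)) text
                       else sprintf("fixture '%s' written to %s", input, output))
      },
      bp_abort("bp_config_error", sprintf(
        "unknown command '%s'; use build, check, summarize or fixture", command))
    )
  }, bp_error = function(cond) {
    list(status = bp_exit_code(cond), message = conditionMessage(cond))
  })
  result
}
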