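# Typed condition helpers.  Every user-facing failure carries one of the
# bp_* classes so callers (and the CLI) can map it to a category/exit code:
#   bp_parse_error, bp_collision_error, bp_orientation_error,
#   bp_config_error, bp_geometry_error, bp_io_error
bp_abort <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "bp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}
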