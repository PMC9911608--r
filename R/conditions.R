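# Classed conditions so callers (and the CLI) can map failures to exit codes.

stop_fretclem <- function(message, class, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "fretclem_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

stop_invalid <- function(message, ...) {
  stop_fretclem(message, "fretclem_invalid_parameter", call = sys.call(-2), ...)
}

stop_insufficient_photons <- function(message, ...) {
  stop_fretclem(message, "fretclem_insufficient_photons", call = sys.call(-2), ...)
}

stop_parse <- function(message, ...) {
  stop_fretclem(message, c("fretclem_parse_error", "fretclem_data_error"),
                call = sys.call(-2), ...)
}

stop_data <- function(message, ...) {
  stop_fretclem(message, "fretclem_data_error", call = sys.call(-2), ...)
}
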