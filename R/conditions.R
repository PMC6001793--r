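# Classed conditions so callers (and the command-line driver) can map
# failure categories to exit codes without parsing messages.

stop_config <- function(msg, ...) {
  stop(structure(class = c("nmr_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("nmr_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_format <- function(msg, ...) {
  stop(structure(class = c("nmr_format_error", "nmr_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

warn_nmr <- function(msg, ...) {
  warning(structure(class = c("nmr_warning", "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}
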