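#' @keywords internal
rfl_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "rfl_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

rfl_format_error    <- function(msg) rfl_error(msg, "rfl_format_error")
rfl_bounds_error    <- function(msg) rfl_error(msg, "rfl_bounds_error")
rfl_parameter_error <- function(msg) rfl_error(msg, "rfl_parameter_error")
rfl_type_error      <- function(msg) rfl_error(msg, "rfl_type_error")
rfl_contract_error  <- function(msg) rfl_error(msg, "rfl_contract_error")
rfl_config_error    <- function(msg) rfl_error(msg, "rfl_config_error")
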