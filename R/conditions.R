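# Classed conditions so callers (and the CLI) can map failures to causes.
# Hierarchy: every error carries "raman_error" plus one specific class.

raman_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "raman_error", "error")))
}

abort_format       <- function(msg) raman_abort(msg, "raman_format_error")
abort_validation   <- function(msg) raman_abort(msg, "raman_validation_error")
abort_config       <- function(msg) raman_abort(msg, "raman_config_error")
abort_insufficient <- function(msg) raman_abort(msg, "raman_insufficient_data_error")
abort_degenerate   <- function(msg) raman_abort(msg, "raman_degenerate_error")
abort_io           <- function(msg) raman_abort(msg, "raman_io_error")
abort_undefined    <- function(msg) raman_abort(msg, "raman_undefined_error")

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(sprintf("`%s` must be a single finite number", name))
  if (strict_lower && x <= lower)
    abort_config(sprintf("`%s` must be > %g", name, lower))
  if (!strict_lower && x < lower)
    abort_config(sprintf("`%s` must be >= %g", name, lower))
  if (x > upper)
    abort_config(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}
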