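# condition helpers: every user-facing failure carries a typed class so
# callers (and tests) can distinguish resolution/geometry/parameter/
# numerical/format errors.

mm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "morphomech_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

mm_resolution_error <- function(msg, ...) mm_stop("morphomech_resolution_error", msg, ...)
mm_geometry_error   <- function(msg, ...) mm_stop("morphomech_geometry_error", msg, ...)
mm_parameter_error  <- function(msg, ...) mm_stop("morphomech_parameter_error", msg, ...)
mm_numerical_error  <- function(msg, ...) mm_stop("morphomech_numerical_error", msg, ...)
mm_format_error     <- function(msg, ...) mm_stop("morphomech_format_error", msg, ...)

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mm_parameter_error("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) mm_parameter_error("'%s' must be > 0", name)
  if (nonneg && x < 0) mm_parameter_error("'%s' must be >= 0", name)
  invisible(x)
}
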