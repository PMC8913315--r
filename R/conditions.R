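# Condition classes used across the package. Every error signalled here
# inherits from "xk_error" so callers (and the CLI wrapper) can map a failure
# class to an exit status without string-matching messages.

xk_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "xk_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_invalid_argument <- function(message) {
  xk_stop(message, "xk_invalid_argument", call = sys.call(-1))
}

stop_insufficient_data <- function(message) {
  xk_stop(message, c("xk_insufficient_data", "xk_data_error"),
          call = sys.call(-1))
}

stop_missing_data <- function(message) {
  xk_stop(message, c("xk_missing_data", "xk_data_error"), call = sys.call(-1))
}

stop_parse_error <- function(message) {
  xk_stop(message, c("xk_parse_error", "xk_data_error"), call = sys.call(-1))
}

stop_schema_error <- function(message) {
  xk_stop(message, c("xk_schema_error", "xk_parse_error", "xk_data_error"),
          call = sys.call(-1))
}

stop_config_error <- function(message) {
  xk_stop(message, "xk_config_error", call = sys.call(-1))
}

stop_numeric_error <- function(message) {
  xk_stop(message, "xk_numeric_error", call = sys.call(-1))
}

warn_xk <- function(message, class) {
  warning(warningCondition(message, class = c(class, "xk_warning")))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
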