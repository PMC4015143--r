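# Internal helpers shared across modules.

# Classed error conditions so callers and the CLI can map failures to exit
# codes and tests can match on failure kind rather than message wording.
stop_dnam <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dnamclock_error", "error"),
                      call = call))
}

format_error     <- function(msg) stop_dnam("dnamclock_format_error", msg)
bounds_error     <- function(msg) stop_dnam("dnamclock_bounds_error", msg)
parse_error      <- function(msg) stop_dnam("dnamclock_parse_error", msg)
validation_error <- function(msg) stop_dnam("dnamclock_validation_error", msg)
domain_error     <- function(msg) stop_dnam("dnamclock_domain_error", msg)
config_error     <- function(msg) stop_dnam("dnamclock_config_error", msg)
data_error       <- function(msg) stop_dnam("dnamclock_data_error", msg)
io_error         <- function(msg) stop_dnam("dnamclock_io_error", msg)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
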