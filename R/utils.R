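# internal helpers shared across the pipeline

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable, machine-greppable log lines.  Everything the pipeline wants to
# surface (dropped model terms, capped LODs, clipped variances, skipped
# markers) goes through here so downstream logs can be filtered by prefix.
iq_log <- function(tag, ...) {
  message(sprintf("[ionqtl] %s: %s", tag, paste0(...)))
}

stop_arg <- function(...) stop(..., call. = FALSE)

# assert a single positive / finite scalar
check_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(name, " must be a single finite number")
  if (positive && x <= 0) stop_arg(name, " must be > 0")
  if (integerish && x != round(x)) stop_arg(name, " must be an integer")
  invisible(x)
}

# Derive a reproducible sub-seed from a base seed and an offset, keeping the
# result inside the 32-bit integer range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 9973 * as.numeric(offset)) %% 2147483647L)
}
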