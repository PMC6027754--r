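# Internal helpers shared across modules.

# Byte-order (C locale) sorting so output is identical across locales.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aggregation levels, most detailed to most compressed.
AGGREGATION_LEVELS <- c("AL0", "AL1", "AL2", "AL3")

level_rank <- function(level) {
  r <- match(level, AGGREGATION_LEVELS) - 1L
  if (anyNA(r)) stop("unknown aggregation level: ", paste(level[is.na(r)], collapse = ", "))
  r
}

NODE_KINDS <- c("TOOL", "FILE", "RAW")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Condition class for usage errors (CLI maps these to exit code 2).
usage_error <- function(msg) {
  structure(
    class = c("provdag_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
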