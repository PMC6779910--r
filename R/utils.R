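# Internal helpers: condition classes and small utilities.

# Input/config errors carry class "imagemine_input_error" so callers (and the
# CLI, which maps them to exit code 2) can distinguish bad input from bugs.
abort_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("imagemine_input_error", "imagemine_error")))
}

abort <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "imagemine_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Byte-wise (C locale) lexicographic sort, independent of the session locale.
sort_bytewise <- function(x) sort(x, method = "radix")

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

stopifnot_count <- function(x, name, min = 0L) {
  if (!is_count(x, min)) {
    abort_input(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}
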