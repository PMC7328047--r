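# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# sample standard deviation that returns 0 for a single value
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
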