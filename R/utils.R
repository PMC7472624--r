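## internal helpers shared across modules

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict && x <= lower) stop_field(field, sprintf("must be > %g", lower))
  if (!strict && x < lower) stop_field(field, sprintf("must be >= %g", lower))
  invisible(x)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

## deterministic child seed derived from a master seed; kept inside 32-bit range
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 69069 + as.double(i) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
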