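#' @keywords internal
"_PACKAGE"

# Half-up rounding to `digits` decimals. base::round() rounds half to even,
# which would turn 23.525 into 23.52; summary percentages follow the common
# half-up convention instead.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible integer sub-seed for a named generator stream, so
# adding a generator never perturbs another stream's draws. Kept < 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared message sink: the pipeline logs structured one-liners; tests can
# silence them with suppressMessages().
iscreen_log <- function(...) {
  message("[iscreen] ", sprintf(...))
}

assert_prob <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("%s must lie in [0, 1]; offending value %g", name,
                 x[bad][1]), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("%s contains missing values", name), call. = FALSE)
  }
  invisible(x)
}
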