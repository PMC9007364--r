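
# internal input-checking helpers ------------------------------------------

stop_invalid <- function(msg, class = "sagdiv_invalid_input") {
  abort(msg, class = class)
}

check_fraction <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0 | x > 1) else is.na(x) | x < 0 | x > 1
  if (any(bad)) {
    stop_invalid(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# deterministic RNG scope: all generators derive their stream from an
# explicit seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

BASES <- c("A", "C", "G", "T")

# map a seed plus a small offset to a distinct, valid 32-bit seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 113L + offset) %% .Machine$integer.max)
}
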