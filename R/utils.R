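# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a root seed; keeps independently
# callable generator stages reproducible while letting a single root seed
# drive a whole run. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c("population", "encounters", "outcomes", "pipeline", "recovery")
  k <- match(stage, stages)
  if (is.na(k)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# zero-padded identifier like "h07", "p0042"
pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"), i)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) == 0L || any(is.na(x)) || any(x < min) ||
      any(x != floor(x)))
    stopf("configuration error: '%s' must be integer(s) >= %d", name, min)
  invisible(as.integer(x))
}

check_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("configuration error: '%s' must be a proportion in [0, 1]", name)
  invisible(x)
}

# integer range spec: either a single value or c(lo, hi)
draw_range <- function(n, rng) {
  if (length(rng) == 1L) rep.int(as.integer(rng), n)
  else sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

as_date_window <- function(window) {
  w <- as.Date(window)
  if (length(w) != 2L || any(is.na(w)))
    stopf("configuration error: window must be two parseable dates")
  if (w[1] > w[2])
    stopf("configuration error: window start %s is after end %s", w[1], w[2])
  w
}
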