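# internal helpers

# Run code with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# linear interpolation that errors outside the range instead of returning NA
interp_strict <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stopf("requested %s outside the covered range [%g, %g]", what, min(x), max(x))
  stats::approx(x, y, xout = clamp(xout, min(x), max(x)), ties = "ordered")$y
}
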