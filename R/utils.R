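#' @keywords internal
"_PACKAGE"

## Internal helpers: argument checking and reproducible RNG substreams.

stop_scanstab <- function(msg, class) {
  stop(structure(class = c(class, "scanstab_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "scanstab_usage_error") {
  if (!isTRUE(ok)) stop_scanstab(msg, class)
  invisible(TRUE)
}

## Deterministic 31-bit hash of a character key, used to derive per-acquisition
## RNG substreams from one master seed.  Exact in double arithmetic: the state
## is kept below 2^31 at every step.
key_hash <- function(key) {
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  h
}

## Substream seed for (master seed, key).  Stays in [0, 2^31 - 2].
substream_seed <- function(seed, key) {
  (as.numeric(seed) %% 2147483647 * 48271 + key_hash(key)) %% 2147483647
}

## Run `expr` under a local RNG state seeded from (seed, key); the caller's
## RNG state is untouched, so subsets of a dataset are reproducible on their own.
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(substream_seed(seed, key)))
  expr
}

## Full-precision number formatting so CSV round-trips are bit-identical.
format_full <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
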