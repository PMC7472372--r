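# Internal helpers: classed error conditions and reproducible local RNG.

stop_fixmon <- function(subclass, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("fixmon_", subclass, "_error"), "fixmon_error",
              "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. Used by every simulator so that scenario$seed fully determines
# outputs (seed-determinism contract).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific seed from a base seed and a small integer tag,
# keeping the result inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(tag)) %% 2147483647)
}
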