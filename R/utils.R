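# Internal seeding helpers: every stochastic stage derives its own seed from
# the caller's seed so whole studies are reproducible from one master seed,
# and the global RNG state is never disturbed.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

# deterministic 32-bit-safe child seed from (seed, stage index)
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (kk in c(k, 7L)) {
    s <- (s * 48271 + as.double(kk) * 3019) %% 2147483647
  }
  as.integer(s)
}
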