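# Shared fixtures: built once per test run, in code (no data files).

default_pool <- build_pool(pool_params())

# a small, fast pool for pipeline-level tests
tiny_pool <- build_pool(pool_params(n_units = 20L, fibers_min = 10L,
                                    fibers_max = 200L))

# a quick grid-session config: short contractions, full 13 x 6 grid
quick_session_config <- function(...) {
  grid_session_config(duration = 1.5, segment = 1, ...)
}

# noiseless power-law level series
power_series <- function(b, a, n = 10, channels = 1) {
  x <- seq(0.1, 1, length.out = n)
  level_series(x, matrix(rep(a * x^b, channels), ncol = channels))
}
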