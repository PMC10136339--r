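test_that("RMS amplitude matches hand-computed values", {
  expect_equal(emg_rms(rep(-3, 10)), 3)
  expect_equal(emg_rms(c(3, -4)), sqrt(12.5))
  t <- seq(0, 1, length.out = 1001)[-1001]
  expect_equal(emg_rms(2 * sin(2 * pi * 5 * t)), 2 / sqrt(2), tolerance = 1e-6)
  expect_error(emg_rms(numeric(0)), "empty")
})

test_that("log-log regression recovers exact power laws", {
  f <- fit_loglog(power_series(1, 1))
  expect_equal(f$b, 1)
  expect_equal(f$ln_a, 0)
  x <- seq(0.2, 2, length.out = 10)
  f2 <- fit_loglog(x, 2 * x^1.5)
  expect_equal(f2$b, 1.5)
  expect_equal(f2$ln_a, log(2))
  expect_equal(f2$r_squared, 1)
})

test_that("log-log regression is exact for random power laws (property)", {
  set.seed(42)
  for (k in 1:25) {
    b <- runif(1, 0.5, 2); a <- runif(1, 0.1, 10)
    x <- sort(runif(8, 0.05, 5))
    f <- fit_loglog(x, a * x^b)
    expect_equal(f$b, b, tolerance = 1e-10)
    expect_equal(f$ln_a, log(a), tolerance = 1e-8)
  }
})

test_that("noisy power-law slope matches an independent regression oracle", {
  set.seed(7)
  x <- seq(0.1, 1, length.out = 10)
  y <- 1.3 * x^1.2 * exp(rnorm(10, 0, 0.05))
  ours <- fit_loglog(x, y)
  oracle <- lm(log(y) ~ log(x))
  expect_equal(ours$b, unname(coef(oracle)[2]))
  expect_equal(ours$ln_a, unname(coef(oracle)[1]))
  expect_equal(ours$r_squared, summary(oracle)$r.squared)
})

test_that("normalization changes the intercept but never the slope", {
  set.seed(3)
  x <- seq(0.1, 1, length.out = 10)
  y <- 0.8 * x^1.4 * exp(rnorm(10, 0, 0.1))
  s <- level_series(x, y)
  ns <- normalize_series(s)
  expect_equal(fit_loglog(s)$b, fit_loglog(ns)$b, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fit_loglog(s)$ln_a, fit_loglog(ns)$ln_a)))
})

test_that("regression rejects degenerate inputs", {
  expect_error(fit_loglog(c(1, 2, 3), c(1, -1, 2)), "positive")
  expect_error(fit_loglog(rep(2, 5), rep(1, 5)), "degenerate")
  expect_error(level_series(c(1, 2), matrix(1, 2, 1)), "3 levels")
})

test_that("slope maps lay channels out in grid coordinates", {
  el <- electrode_grid(3, 2, 8)
  x <- seq(0.1, 1, length.out = 5)
  b_true <- c(0.8, 1.0, 1.2, 1.4, 1.6, 1.8)
  rms <- sapply(b_true, function(b) x^b)
  m <- slope_map(level_series(x, rms), el)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[cbind(el$row, el$col)], b_true, tolerance = 1e-10)
  # constant session gives a constant map
  mc <- slope_map(level_series(x, sapply(1:6, function(i) x^1.1)), el)
  expect_true(all(abs(unclass(mc) - 1.1) < 1e-10))
})

test_that("slope maps are permutation-equivariant in the channels", {
  el <- electrode_grid(2, 3, 8)
  x <- seq(0.1, 1, length.out = 6)
  rms <- sapply(seq(0.9, 1.4, by = 0.1), function(b) x^b)
  m1 <- slope_map(level_series(x, rms), el)
  perm <- c(4, 2, 6, 1, 3, 5)
  el2 <- el[perm, ]; el2$channel <- seq_len(6)
  m2 <- slope_map(level_series(x, rms[, perm]), el2)
  v1 <- unclass(m1); attr(v1, "fits") <- NULL
  v2 <- unclass(m2); attr(v2, "fits") <- NULL
  expect_equal(v1, v2)
})

test_that("failed channels are marked missing rather than fatal", {
  el <- electrode_grid(1, 3, 8)
  x <- seq(0.1, 1, length.out = 5)
  rms <- cbind(x^1.2, rep(1, 5), x^0.9)  # middle channel constant
  rms[2, 2] <- -1                        # and invalid
  m <- suppressWarnings(slope_map(level_series(x, abs(rms)), el))
  expect_false(anyNA(m[1, c(1, 3)]))
})

test_that("whole-array slope equals the fit of the mean-RMS series", {
  x <- seq(0.1, 1, length.out = 6)
  rms <- sapply(c(1.0, 1.2, 1.4), function(b) x^b)
  direct <- fit_loglog(x, rowMeans(rms))$b
  # identical to first averaging the channels into one series
  expect_equal(fit_loglog(level_series(x, rowMeans(rms)))$b, direct)
})

test_that("regional means average the named channel blocks", {
  el <- electrode_grid(13, 6, 8)
  x <- seq(0.1, 1, length.out = 5)
  # checkerboard of two slope values
  b_grid <- matrix(rep_len(c(1, 2), 13 * 6), 13, 6)
  rms <- sapply(seq_len(nrow(el)), function(ch)
    x^b_grid[el$row[ch], el$col[ch]])
  m <- slope_map(level_series(x, rms), el)
  rg <- region_spec()
  expect_equal(region_mean(m, "proximal", rg), mean(b_grid[3:4, ]))
  expect_equal(region_mean(m, "distal", rg), mean(b_grid[10:11, ]))
  expect_equal(region_mean(m, "lateral", rg), mean(b_grid[, 1:2]))
  expect_equal(region_mean(m, "medial", rg), mean(b_grid[, 5:6]))
  # single-channel region
  expect_equal(region_mean(m, list(rows = 1, cols = 1)), b_grid[1, 1])
  expect_error(region_mean(m, list(rows = 99)), "exceed")
})
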