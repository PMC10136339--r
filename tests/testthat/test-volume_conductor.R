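test_that("tripole construction enforces charge balance", {
  expect_error(tripole_spec(c(1, -2, 1.5)), "charge balance")
  tp <- tripole_spec()
  expect_equal(sum(tp$amplitudes), 0)
  expect_equal(tp$offsets, c(0, 2, 4))
})

test_that("point-source potential matches the closed form", {
  g <- muscle_geometry()
  expect_equal(point_source_potential(1, 0, 10, 0, g),
               1 / (2 * pi * 0.06 * sqrt(5.5 * 100)))
  expect_error(point_source_potential(1, 0, 0, 0, g), "degenerate")
})

test_that("single-fiber potentials decay with depth and scale linearly", {
  g <- muscle_geometry()
  w5 <- sfap(c(0, 5), c(0, 10), geometry = g)
  w10 <- sfap(c(0, 10), c(0, 10), geometry = g)
  expect_gt(diff(range(w5)), diff(range(w10)))  # doubling depth shrinks p2p
  # linearity in pole strength
  w2 <- sfap(c(0, 5), c(0, 10), tripole = tripole_spec(scale = 3), geometry = g)
  expect_equal(w2, 3 * w5)
  # potential vanishes before generation and after extinction
  expect_equal(w5[1], 0)
  expect_equal(w5[length(w5)], 0, tolerance = 1e-12)
})

test_that("translation symmetry: common x shift leaves the waveform unchanged", {
  g <- muscle_geometry()
  w <- sfap(c(2, 8), c(1, 15), geometry = g)
  w_shift <- sfap(c(2 + 4, 8), c(1 + 4, 15), geometry = g)
  expect_equal(w, w_shift)
})

test_that("fiber placement fills the territory at the target density", {
  g <- muscle_geometry()
  one <- place_fibers(c(0, 12), 1, g, seed = 2)
  expect_equal(nrow(one), 1)
  expect_lt(sqrt(sum((one[1, ] - c(0, 12))^2)), territory_radius <- 0.2)
  big <- place_fibers(c(0, 14), 2137, g, seed = 3)
  # all inside the muscle cross-section
  r2 <- big[, "x"]^2 + (big[, "depth"] - 15)^2
  expect_true(all(r2 < 12^2))
  # empirical density within 10% of 20 fibers/mm^2 (disc fully inside muscle)
  mid <- place_fibers(c(0, 15), 600, g, seed = 4)
  rad <- sqrt(600 / (pi * 20))
  inside <- sum(mid[, "x"]^2 + (mid[, "depth"] - 15)^2 <= (0.8 * rad)^2)
  expect_equal(inside / (pi * (0.8 * rad)^2), 20, tolerance = 0.1)
  expect_error(place_fibers(c(0, 40), 10, g, seed = 1), "outside")
})

test_that("depth assignment recovers the condition's size-depth regression slope", {
  pool <- default_pool
  slopes <- sapply(1:6, function(s) {
    c(attr(assign_depths(pool, "superficial", seed = s), "fitted_slope"),
      attr(assign_depths(pool, "random", seed = s), "fitted_slope"),
      attr(assign_depths(pool, "deep", seed = s), "fitted_slope"))
  })
  expect_equal(mean(slopes[1, ]), -0.13, tolerance = 0.15)
  expect_lt(abs(mean(slopes[2, ])), 0.03)
  expect_equal(mean(slopes[3, ]), 0.12, tolerance = 0.15)
  expect_true(all(slopes[1, ] < 0))
  expect_true(all(slopes[3, ] > 0))
  # depths stay inside the muscle
  d <- assign_depths(pool, "superficial", seed = 9)
  expect_true(all(d$depth > 3 & d$depth < 27))
})

test_that("motor unit potentials are sums of fiber potentials", {
  g <- muscle_geometry()
  one_fiber <- matrix(c(1, 9), 1, dimnames = list(NULL, c("x", "depth")))
  expect_equal(drop(muap(one_fiber, c(0, 12), geometry = g)),
               sfap(c(1, 9), c(0, 12), geometry = g))
  fa <- place_fibers(c(-2, 10), 40, g, seed = 5)
  fb <- place_fibers(c(3, 13), 60, g, seed = 6)
  expect_equal(muap(rbind(fa, fb), c(0, 12), geometry = g),
               muap(fa, c(0, 12), geometry = g) +
                 muap(fb, c(0, 12), geometry = g))
})

test_that("shallower units project larger potentials to the surface", {
  g <- muscle_geometry()
  set.seed(1)
  ang <- runif(300, 0, 2 * pi); rad <- 2 * sqrt(runif(300))
  shallow <- cbind(x = rad * cos(ang), depth = 5 + rad * sin(ang))
  deep <- cbind(x = shallow[, 1], depth = 15 + rad * sin(ang))
  m_sh <- muap(shallow, c(0, 10), geometry = g)
  m_dp <- muap(deep, c(0, 10), geometry = g)
  expect_gt(diff(range(m_sh)), diff(range(m_dp)))
})

test_that("EMG synthesis is a sparse superposition of MUAP trains", {
  pool <- tiny_pool
  pl <- place_pool(pool, "random", seed = 4)
  el <- matrix(c(0, 10), 1, 2)
  tm <- muap_templates(pl, el, fs = 2000)
  # silence
  silent <- structure(list(excitation = 0, duration = 0.5,
                           spike_times = rep(list(numeric(0)), 20)),
                      class = "spike_trains")
  rec0 <- synthesize_emg(silent, tm, 2000)
  expect_true(all(rec0$signals == 0))
  # one spike of one unit: time-shifted template
  one <- structure(list(excitation = 10, duration = 0.5,
                        spike_times = c(list(0.1),
                                        rep(list(numeric(0)), 19))),
                   class = "spike_trains")
  rec1 <- synthesize_emg(one, tm, 2000)
  at <- round(0.1 * 2000) + 1
  nk <- nrow(tm[[1]])
  expect_equal(rec1$signals[at:(at + nk - 1), 1], tm[[1]][, 1])
  expect_true(all(rec1$signals[1:(at - 1), 1] == 0))
  # spikes past the end are dropped with a warning
  late <- structure(list(excitation = 10, duration = 0.5,
                         spike_times = c(list(c(0.1, 0.9)),
                                         rep(list(numeric(0)), 19))),
                    class = "spike_trains")
  expect_warning(synthesize_emg(late, tm, 2000, duration = 0.5), "dropped")
})

test_that("EMG amplitude grows with excitation", {
  pool <- default_pool
  pl <- place_pool(pool, "random", seed = 21)
  tm <- muap_templates(pl, matrix(c(0, 10), 1, 2), fs = 2000)
  rms_at <- function(e, seed) {
    tr <- generate_spike_trains(pool, e, 1.5, seed = seed)
    rec <- synthesize_emg(tr, tm, 2000)
    emg_rms(rec$signals[1001:3000, 1])
  }
  ratio <- sapply(1:5, function(s) rms_at(100, s) / rms_at(10, s + 50))
  expect_true(all(ratio > 1))
})

test_that("superficial placements amplify high-excitation EMG growth over deep ones", {
  pool <- default_pool
  growth <- function(cond, seed) {
    pl <- place_pool(pool, cond, seed = seed)
    tm <- muap_templates(pl, matrix(c(0, 10), 1, 2), fs = 2000)
    r <- sapply(c(20, 100), function(e) {
      tr <- generate_spike_trains(pool, e, 1.5, seed = seed * 1000 + e)
      rec <- synthesize_emg(tr, tm, 2000)
      emg_rms(rec$signals[1001:3000, 1])
    })
    r[2] / r[1]
  }
  wins <- sapply(1:10, function(s) growth("superficial", s) > growth("deep", s))
  expect_gt(mean(wins), 0.5)
})

test_that("EMG recordings round-trip through CSV bit-exactly", {
  pool <- tiny_pool
  pl <- place_pool(pool, "random", seed = 8)
  el <- electrode_grid(2, 2, 8)
  tm <- muap_templates(pl, el, fs = 1000)
  tr <- generate_spike_trains(pool, 50, 0.5, seed = 9)
  rec <- synthesize_emg(tr, tm, 1000, electrodes = el)
  path <- file.path(withr::local_tempdir(), "emg.csv")
  write_emg_csv(rec, path)
  back <- read_emg_csv(path)
  expect_identical(back$signals, rec$signals)
  expect_equal(back$fs, rec$fs)
})
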