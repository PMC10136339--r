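test_that("excitation calibration hits the requested force fractions", {
  pool <- default_pool
  targets <- c(20, 40, 60, 80, 100)
  exc <- calibrate_excitation_for_mvc(pool, targets)
  expect_equal(exc[5], 100)
  expect_true(all(diff(exc) > 0))
  # closed-loop: noise-free force at the returned excitation is on target
  f_max <- emgforce:::expected_mean_force(pool, 100)
  for (k in 1:4)
    expect_equal(emgforce:::expected_mean_force(pool, exc[k]) / f_max,
                 targets[k] / 100, tolerance = 0.01)
})

test_that("a single-repetition study yields one b per condition and no ANOVA", {
  cfg <- sim_study_config(conditions = c("superficial", "deep"),
                          repetitions = 1, excitations = seq(20, 100, 20),
                          duration = 1, window = 0.8, seed = 5)
  res <- run_depth_condition_study(cfg)
  expect_named(res$b, c("superficial", "deep"))
  expect_length(res$b$superficial, 1)
  expect_null(res$anova)
  expect_null(res$normality)
})

test_that("studies are bit-identical under the same master seed", {
  cfg <- sim_study_config(conditions = c("superficial", "deep"),
                          repetitions = 2, excitations = seq(20, 100, 20),
                          duration = 1, window = 0.8, seed = 99)
  r1 <- run_depth_condition_study(cfg)
  r2 <- run_depth_condition_study(cfg)
  expect_identical(r1, r2)
  r3 <- run_depth_condition_study(sim_study_config(
    conditions = c("superficial", "deep"), repetitions = 2,
    excitations = seq(20, 100, 20), duration = 1, window = 0.8, seed = 100))
  expect_false(identical(r1$b, r3$b))
})

test_that("condition means order superficial > random > deep", {
  cfg <- sim_study_config(repetitions = 4, seed = 17,
                          duration = 1.5, window = 1)
  res <- run_depth_condition_study(cfg)
  expect_gt(res$mean["superficial"], res$mean["random"])
  expect_gt(res$mean["random"], res$mean["deep"])
})

test_that("grid sessions use the stated analysis segment (2 s at 2048 Hz)", {
  cfg <- grid_session_config()
  idx <- emgforce:::window_index(round(cfg$fs * cfg$duration), cfg$fs,
                                 cfg$duration, cfg$segment)
  expect_length(idx, 4096)
  expect_equal(cfg$fs, 2048)
  expect_equal(cfg$mvc_levels, c(20, 40, 60, 80))
})

test_that("grid session generation is deterministic in the subject seed", {
  cfg <- quick_session_config(seed = 3)
  s1 <- generate_grid_session(cfg, subject_seed = 42)
  s2 <- generate_grid_session(cfg, subject_seed = 42)
  expect_identical(s1$recordings[[1]]$signals, s2$recordings[[1]]$signals)
  expect_identical(s1$force[[2]]$samples, s2$force[[2]]$samples)
  s3 <- generate_grid_session(cfg, subject_seed = 43)
  expect_false(identical(s1$recordings[[1]]$signals,
                         s3$recordings[[1]]$signals))
})

test_that("a zero gradient without subject jitter gives mirror-symmetric regions", {
  cfg <- quick_session_config(depth_gradient = 0, gradient_jitter_sd = 0)
  s <- generate_grid_session(cfg, subject_seed = 7)
  res <- analyze_grid_session(list(s))
  expect_equal(res$per_subject$proximal, res$per_subject$distal,
               tolerance = 1e-12)
})

test_that("recovered regional difference is monotone in the generator gradient", {
  diffs <- sapply(c(0, 0.06, 0.12), function(g) {
    cfg <- quick_session_config(depth_gradient = g, n_subjects = 10, seed = 31)
    res <- analyze_grid_session(generate_grid_cohort(cfg))
    mean(res$per_subject$proximal - res$per_subject$distal)
  })
  expect_true(all(diff(diffs) > 0))
  expect_lt(abs(diffs[1]), 0.03)   # null is centred near zero
  expect_gt(diffs[3], 0.05)        # strong gradient is clearly recovered
})

test_that("whole-array slope of a pure power-law session is the exponent", {
  # bypass the simulator: construct a session-like series directly
  x <- seq(0.2, 1, length.out = 4)
  rms <- matrix(rep(x^1.2, 5), ncol = 5)
  expect_equal(fit_loglog(x, rowMeans(rms))$b, 1.2)
})

test_that("sessions round-trip through the on-disk format bit-exactly", {
  cfg <- quick_session_config(rows = 4, cols = 2, seed = 2)
  s <- generate_grid_session(cfg, subject_seed = 12)
  dir <- file.path(withr::local_tempdir(), "subj01")
  write_grid_session(s, dir)
  back <- read_grid_session(dir)
  expect_identical(back$recordings[[1]]$signals, s$recordings[[1]]$signals)
  expect_identical(back$force[[3]]$samples, s$force[[3]]$samples)
  expect_equal(back$mvc_levels, s$mvc_levels)
  expect_equal(back$ground_truth$subject_gradient,
               s$ground_truth$subject_gradient)
  # a missing level file is reported by name
  unlink(file.path(dir, "level_040.csv"))
  expect_error(read_grid_session(dir), "40")
})
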