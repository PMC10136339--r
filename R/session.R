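#' Configuration of a synthetic high-density grid session
#'
#' Describes the emulated isometric-contraction protocol recorded with a
#' high-density surface electrode grid: grid geometry, sampling rate,
#' contraction levels, durations, cohort size, and the proximal-distal
#' depth-gradient parameter that is the generator's ground truth for regional
#' slope differences.
#'
#' The default grid is one logical array of 13 rows (along the fiber
#' direction, 8 mm pitch, centred over the innervation zone) by 6 columns
#' (across the muscle), monopolar at 2048 Hz. Negative z is the proximal
#' side, so grid rows 1-6 are proximal and rows 8-13 distal.
#'
#' `depth_gradient` is the fiber inclination (mm of depth per mm along z)
#' applied to the largest unit and scaled down with normalised twitch force
#' for smaller units: with a positive gradient, large units lie progressively
#' shallower toward the proximal side, which raises the log-log slope b on
#' proximal rows relative to distal rows. Zero removes the regional
#' asymmetry.
#'
#' @param rows,cols,pitch grid layout (13 x 6, 8 mm).
#' @param fs sampling rate, Hz (2048).
#' @param mvc_levels contraction levels, %MVC (20, 40, 60, 80).
#' @param duration contraction length, s (default 5).
#' @param segment analysis segment length, s, centred (default 2).
#' @param n_subjects cohort size (default 9).
#' @param depth_gradient proximal-distal depth gradient, mm/mm (default
#'   0.12).
#' @param gradient_jitter_sd SD of the subject-level jitter added to
#'   `depth_gradient` (default 0.02), the between-subject anatomical
#'   variability of the gradient. With a zero gradient this jitter is what
#'   makes the proximal-distal null distribution non-degenerate (the
#'   centred grid is otherwise mirror-symmetric along the fibers).
#' @param base_condition depth-distribution condition of the subject pools
#'   (default `"random"`).
#' @param strategy,rte_max_fraction pool settings; the default 80%
#'   recruitment range mimics large limb muscles, where recruitment operates
#'   over most of the force range.
#' @param jitter_sd depth jitter SD, see [assign_depths()].
#' @param seed master seed for the cohort.
#' @return A `grid_session_config`.
#' @export
grid_session_config <- function(rows = 13, cols = 6, pitch = 8, fs = 2048,
                                mvc_levels = c(20, 40, 60, 80),
                                duration = 5, segment = 2,
                                n_subjects = 9, depth_gradient = 0.12,
                                gradient_jitter_sd = 0.02,
                                base_condition = "random",
                                strategy = "reverse_onion_skin",
                                rte_max_fraction = 0.8,
                                jitter_sd = 2, seed = 1L) {
  stopifnot(segment <= duration, !is.unsorted(mvc_levels, strictly = TRUE),
            length(mvc_levels) >= 3, n_subjects >= 1)
  structure(list(rows = rows, cols = cols, pitch = pitch, fs = fs,
                 mvc_levels = mvc_levels, duration = duration,
                 segment = segment, n_subjects = n_subjects,
                 depth_gradient = depth_gradient,
                 gradient_jitter_sd = gradient_jitter_sd,
                 base_condition = base_condition, strategy = strategy,
                 rte_max_fraction = rte_max_fraction,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "grid_session_config")
}

#' Generate one synthetic grid session (one subject)
#'
#' Builds a subject-specific motor unit placement (geometry seed and
#' per-unit fiber inclination set by the depth gradient), maps the %MVC
#' targets onto the excitation axis, and synthesises monopolar EMG at every
#' grid electrode plus the whole-muscle force trace for each contraction
#' level. The generator's ground-truth parameters are stored in the session
#' for parameter-recovery checks.
#'
#' @param config a [grid_session_config()].
#' @param subject_seed integer seed for this subject.
#' @return A `grid_session`: list with `recordings` (one `emg_recording` per
#'   level), `force` (one `force_trace` per level), `electrodes`,
#'   `mvc_levels`, `excitations`, `config`, `ground_truth`.
#' @export
generate_grid_session <- function(config = grid_session_config(),
                                  subject_seed) {
  stopifnot(inherits(config, "grid_session_config"))
  if (missing(subject_seed)) stop("an explicit subject seed is required")
  pool <- build_pool(pool_params(strategy = config$strategy,
                                 rte_max_fraction = config$rte_max_fraction))
  geometry <- muscle_geometry()
  tripole <- tripole_spec()
  p_norm <- pool$p / max(pool$p)
  subject_gradient <- config$depth_gradient
  if (config$gradient_jitter_sd > 0) {
    with_local_seed(derive_seed(subject_seed, 13L), {
      subject_gradient <- subject_gradient +
        stats::rnorm(1, 0, config$gradient_jitter_sd)
    })
  }
  tilt <- subject_gradient * p_norm
  placement <- place_pool(pool, config$base_condition, geometry,
                          seed = derive_seed(subject_seed, 11L),
                          depth_tilt = tilt, jitter_sd = config$jitter_sd)
  electrodes <- electrode_grid(config$rows, config$cols, config$pitch)
  templates <- muap_templates(placement, electrodes, tripole, config$fs)
  excitations <- calibrate_excitation_for_mvc(pool, config$mvc_levels)
  recordings <- vector("list", length(config$mvc_levels))
  force <- vector("list", length(config$mvc_levels))
  for (l in seq_along(config$mvc_levels)) {
    trains <- generate_spike_trains(pool, excitations[l], config$duration,
                                    seed = derive_seed(subject_seed, 50L + l))
    recordings[[l]] <- synthesize_emg(trains, templates, config$fs,
                                      electrodes = electrodes)
    force[[l]] <- muscle_force(pool, trains, config$fs)
  }
  structure(list(recordings = recordings, force = force,
                 electrodes = electrodes, mvc_levels = config$mvc_levels,
                 excitations = excitations, config = config,
                 ground_truth = list(depth_gradient = config$depth_gradient,
                                     subject_gradient = subject_gradient,
                                     subject_seed = subject_seed,
                                     fitted_slope = attr(placement$centers,
                                                         "fitted_slope"))),
            class = "grid_session")
}

#' @export
print.grid_session <- function(x, ...) {
  cat(sprintf("Grid session: %d levels (%s %%MVC), %d channels at %g Hz, gradient %g\n",
              length(x$mvc_levels), paste(x$mvc_levels, collapse = "/"),
              nrow(x$electrodes), x$config$fs,
              x$ground_truth$depth_gradient))
  invisible(x)
}

# level series (force + per-channel RMS on the centred analysis segment).
# Channels are demeaned per segment before the RMS: grid recordings emulate
# AC-coupled amplifier hardware, which removes the quasi-static offset of the
# monopolar potential before digitisation.
session_level_series <- function(session) {
  cfg <- session$config
  nlev <- length(session$mvc_levels)
  nch <- nrow(session$electrodes)
  rms <- matrix(NA_real_, nlev, nch)
  force <- numeric(nlev)
  for (l in seq_len(nlev)) {
    sig <- session$recordings[[l]]$signals
    idx <- window_index(nrow(sig), cfg$fs, cfg$duration, cfg$segment)
    seg <- sig[idx, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    rms[l, ] <- sqrt(colMeans(seg^2))
    force[l] <- mean(session$force[[l]]$samples[idx])
  }
  normalize_series(level_series(force, rms, session$mvc_levels))
}

#' Analyze a cohort of grid sessions
#'
#' For each session: per-channel RMS and mean force on the centred analysis
#' segment, normalisation to the maximum level, per-channel log-log slope map,
#' regional means (proximal, distal, lateral, medial) and the whole-array b
#' (fit of the across-channel mean RMS). Across subjects, paired Wilcoxon
#' signed-rank tests compare proximal vs distal and lateral vs medial
#' regional slopes, with effect sizes r = |Z|/sqrt(n).
#'
#' @param sessions list of `grid_session` objects (>= 5 for the Wilcoxon
#'   tests).
#' @param regions a [region_spec()].
#' @return A `grid_study`: list with `per_subject` (data frame of regional
#'   and whole-array b), `maps` (list of `slope_map`), `tests` (list with
#'   `proximal_vs_distal`, `lateral_vs_medial`).
#' @export
analyze_grid_session <- function(sessions, regions = region_spec()) {
  if (inherits(sessions, "grid_session")) sessions <- list(sessions)
  ns <- length(sessions)
  maps <- vector("list", ns)
  per <- data.frame(subject = seq_len(ns), whole_array = NA_real_,
                    proximal = NA_real_, distal = NA_real_,
                    lateral = NA_real_, medial = NA_real_)
  for (s in seq_len(ns)) {
    series <- session_level_series(sessions[[s]])
    maps[[s]] <- slope_map(series, sessions[[s]]$electrodes)
    mean_rms <- rowMeans(series$rms)
    per$whole_array[s] <- fit_loglog(series$force, mean_rms)$b
    for (rg in c("proximal", "distal", "lateral", "medial"))
      per[[rg]][s] <- region_mean(maps[[s]], rg, regions)
  }
  tests <- NULL
  if (ns >= 5) {
    tests <- list(
      proximal_vs_distal = wilcoxon_signed_rank(per$proximal, per$distal),
      lateral_vs_medial = wilcoxon_signed_rank(per$lateral, per$medial))
  }
  structure(list(per_subject = per, maps = maps, tests = tests,
                 regions = regions),
            class = "grid_study")
}

#' @export
print.grid_study <- function(x, ...) {
  cat(sprintf("Grid study: %d subjects\n", nrow(x$per_subject)))
  m <- colMeans(x$per_subject[, -1, drop = FALSE])
  s <- vapply(x$per_subject[, -1, drop = FALSE], stats::sd, numeric(1))
  for (nm in names(m))
    cat(sprintf("  %-12s b = %.3f +/- %.3f\n", nm, m[nm], s[nm]))
  if (!is.null(x$tests)) {
    pd <- x$tests$proximal_vs_distal
    cat(sprintf("  proximal vs distal: Z = %.2f, p = %.4f, r = %.2f\n",
                pd$z, pd$p_value, pd$effect_size_r))
    lm <- x$tests$lateral_vs_medial
    cat(sprintf("  lateral vs medial:  Z = %.2f, p = %.4f, r = %.2f\n",
                lm$z, lm$p_value, lm$effect_size_r))
  }
  invisible(x)
}

#' Generate a whole cohort of grid sessions
#'
#' Subjects differ by their geometry/discharge seeds, derived from the
#' config's master seed.
#'
#' @param config a [grid_session_config()].
#' @return List of `grid_session` objects of length `config$n_subjects`.
#' @export
generate_grid_cohort <- function(config = grid_session_config()) {
  lapply(seq_len(config$n_subjects), function(s)
    generate_grid_session(config, subject_seed = derive_seed(config$seed,
                                                             500L + s)))
}

#' Write / read a grid session directory
#'
#' One directory per subject: per-level EMG CSVs (`level_<pct>.csv` with JSON
#' sidecars), per-level force CSVs, and `meta.json` holding the layout,
#' sampling rate, levels, seeds and generator ground truth.
#'
#' @param session a `grid_session`.
#' @param dir directory to create.
#' @return `write_grid_session()` returns `dir` invisibly;
#'   `read_grid_session()` returns a `grid_session`.
#' @export
write_grid_session <- function(session, dir) {
  stopifnot(inherits(session, "grid_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in seq_along(session$mvc_levels)) {
    pct <- session$mvc_levels[l]
    write_emg_csv(session$recordings[[l]],
                  file.path(dir, sprintf("level_%03d.csv", pct)))
    write_force_csv(session$force[[l]],
                    file.path(dir, sprintf("force_%03d.csv", pct)))
  }
  cfg <- unclass(session$config)
  meta <- list(mvc_levels = session$mvc_levels,
               excitations = session$excitations,
               config = cfg, ground_truth = session$ground_truth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_grid_session
#' @param dir session directory written by `write_grid_session()`.
#' @export
read_grid_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("not a session directory: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  config <- do.call(grid_session_config,
                    meta$config[setdiff(names(meta$config), character())])
  recordings <- list(); force <- list()
  for (l in seq_along(meta$mvc_levels)) {
    pct <- meta$mvc_levels[l]
    f <- file.path(dir, sprintf("level_%03d.csv", pct))
    if (!file.exists(f))
      stop(sprintf("session %s is missing the %d%%MVC level file %s",
                   dir, pct, basename(f)))
    recordings[[l]] <- read_emg_csv(f)
    ff <- file.path(dir, sprintf("force_%03d.csv", pct))
    samples <- data.table::fread(ff)[[1]]
    fmeta <- jsonlite::read_json(paste0(ff, ".json"), simplifyVector = TRUE)
    force[[l]] <- structure(list(samples = samples, fs = fmeta$fs,
                                 duration = fmeta$duration),
                            class = "force_trace")
  }
  electrodes <- recordings[[1]]$electrodes
  structure(list(recordings = recordings, force = force,
                 electrodes = electrodes, mvc_levels = meta$mvc_levels,
                 excitations = meta$excitations, config = config,
                 ground_truth = meta$ground_truth),
            class = "grid_session")
}
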