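#' Configuration of the depth-condition simulation study
#'
#' Defines the conditions under which the simulated EMG-force slopes are
#' produced: the depth-distribution conditions to compare, the number of
#' repetitions (independent geometry/discharge realisations), the excitation
#' ladder, and the pool/recording settings.
#'
#' @param conditions subset of `c("superficial", "random", "deep")`.
#' @param repetitions repetitions per condition (default 50).
#' @param excitations excitation levels, % of maximum (default 10-100% in 10%
#'   steps).
#' @param strategy,rte_max_fraction pool settings (defaults: reverse
#'   onion-skin, last unit recruited at 40% excitation).
#' @param duration simulated contraction length per level, s (default 3).
#' @param window analysis window length, s, centred in the contraction
#'   (default 2).
#' @param fs sampling rate, Hz (default 2000).
#' @param electrode skin-plane electrode `c(x, z)`, mm; default on the muscle
#'   midline, 10 mm from the innervation zone along the fibers (off the zone
#'   to avoid generation-phase cancellation directly above it, but close
#'   enough that the volume conductor discriminates source depth sharply).
#' @param jitter_sd depth jitter SD, see [assign_depths()].
#' @param seed master seed; all repetition and stage seeds derive from it.
#' @return A `sim_study_config`.
#' @export
sim_study_config <- function(conditions = c("superficial", "random", "deep"),
                             repetitions = 50L,
                             excitations = seq(10, 100, by = 10),
                             strategy = "reverse_onion_skin",
                             rte_max_fraction = 0.4,
                             duration = 3, window = 2, fs = 2000,
                             electrode = c(0, 10), jitter_sd = 2,
                             seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  stopifnot(repetitions >= 1, length(excitations) >= 3,
            window <= duration, fs > 0)
  structure(list(conditions = conditions, repetitions = as.integer(repetitions),
                 excitations = excitations, strategy = strategy,
                 rte_max_fraction = rte_max_fraction,
                 duration = duration, window = window, fs = fs,
                 electrode = electrode, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_study_config")
}

window_index <- function(n, fs, duration, window) {
  i0 <- floor((duration - window) / 2 * fs) + 1L
  i0:min(n, i0 + round(window * fs) - 1L)
}

#' Run the depth-condition simulation study
#'
#' For every repetition: build the pool, draw unit depths under each
#' condition, simulate discharge trains, whole-muscle force and surface EMG
#' at each excitation level, measure mean force and EMG RMS on the analysis
#' window, normalise both to the maximum level, and fit the log-log
#' EMG-force slope b. Spike trains (and hence forces) are shared across
#' conditions within a repetition, so conditions differ only in motor unit
#' placement — the comparison is paired by design.
#'
#' With >= 2 conditions and >= 2 repetitions the per-condition b samples are
#' compared by one-way ANOVA with Bonferroni-corrected pairwise t tests,
#' preceded by a normality check of each condition's b distribution.
#'
#' @param config a [sim_study_config()].
#' @return An `emg_study`: list with `b` (named list of per-repetition b
#'   vectors), `mean`, `sd`, `normality` (per-condition KS p values), `anova`,
#'   and the `config` echo.
#' @export
run_depth_condition_study <- function(config = sim_study_config()) {
  stopifnot(inherits(config, "sim_study_config"))
  pool <- build_pool(pool_params(strategy = config$strategy,
                                 rte_max_fraction = config$rte_max_fraction))
  geometry <- muscle_geometry()
  tripole <- tripole_spec()
  nlev <- length(config$excitations)
  b <- stats::setNames(
    rep(list(numeric(config$repetitions)), length(config$conditions)),
    config$conditions)
  for (rep_i in seq_len(config$repetitions)) {
    rep_seed <- derive_seed(config$seed, rep_i)
    trains <- lapply(seq_len(nlev), function(l)
      generate_spike_trains(pool, config$excitations[l], config$duration,
                            seed = derive_seed(rep_seed, 1000L + l)))
    force_mean <- vapply(trains, function(tr) {
      f <- muscle_force(pool, tr, config$fs)
      idx <- window_index(length(f$samples), config$fs, config$duration,
                          config$window)
      mean(f$samples[idx])
    }, numeric(1))
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      placement <- place_pool(pool, cond, geometry,
                              seed = derive_seed(rep_seed, 2000L + ci),
                              jitter_sd = config$jitter_sd)
      templates <- muap_templates(placement, matrix(config$electrode, 1, 2),
                                  tripole, config$fs)
      rms <- vapply(seq_len(nlev), function(l) {
        rec <- synthesize_emg(trains[[l]], templates, config$fs)
        idx <- window_index(nrow(rec$signals), config$fs, config$duration,
                            config$window)
        emg_rms(rec$signals[idx, 1])
      }, numeric(1))
      series <- normalize_series(level_series(force_mean, rms,
                                              config$excitations))
      b[[cond]][rep_i] <- fit_loglog(series)$b
    }
  }
  normality <- if (config$repetitions >= 5)
    lapply(b, function(v) ks_normality(v)$p_value) else NULL
  anova <- if (length(b) >= 2 && config$repetitions >= 2)
    anova_bonferroni(b) else NULL
  structure(list(b = b,
                 mean = vapply(b, mean, numeric(1)),
                 sd = vapply(b, stats::sd, numeric(1)),
                 normality = normality, anova = anova, config = config),
            class = "emg_study")
}

#' @export
print.emg_study <- function(x, ...) {
  cat(sprintf("EMG-force slope study: %d repetitions per condition\n",
              x$config$repetitions))
  for (cond in names(x$b))
    cat(sprintf("  %-12s b = %.3f +/- %.3f\n", cond, x$mean[cond], x$sd[cond]))
  if (!is.null(x$anova))
    cat(sprintf("  one-way ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
                x$anova$df[1], x$anova$df[2], x$anova$f, x$anova$overall_p))
  invisible(x)
}

# analytic mean force at constant excitation: each recruited unit contributes
# rate * gain * (twitch area), twitch area = p * (t_contract/1000) * e
expected_mean_force <- function(pool, excitation) {
  rates <- firing_rate(pool, seq_len(pool$params$n_units), excitation)
  on <- rates > 0
  if (!any(on)) return(0)
  g <- isi_gain_vec(pool$t_contract[on], 1000 / rates[on])
  sum(rates[on] * g * pool$p[on] * (pool$t_contract[on] / 1000) * exp(1))
}

isi_gain_vec <- function(t_contract, isi) {
  mapply(isi_gain, t_contract, isi)
}

#' Map %MVC targets onto the excitation axis
#'
#' Finds, by bisection on the noise-free expected force (discharge rates and
#' fusion gains, no inter-spike variability), the excitation level at which
#' the simulated muscle produces each target percentage of its force at 100%
#' excitation. Used to emulate a %MVC contraction protocol with the
#' simulator.
#'
#' @param pool a `mu_pool`.
#' @param target_pcts target forces, % of maximum (in (0, 100]).
#' @param tol relative force tolerance of the bisection (default 1e-3).
#' @return Numeric vector of excitation levels (%), same order as
#'   `target_pcts`.
#' @export
calibrate_excitation_for_mvc <- function(pool, target_pcts, tol = 1e-3) {
  stopifnot(all(target_pcts > 0), all(target_pcts <= 100))
  f_max <- expected_mean_force(pool, 100)
  grid <- vapply(seq(0, 100, by = 5), function(e) expected_mean_force(pool, e),
                 numeric(1))
  if (any(diff(grid) < -1e-9 * f_max))
    stop("expected force is not monotone in excitation")
  vapply(target_pcts, function(pct) {
    if (pct >= 100) return(100)
    target <- pct / 100 * f_max
    stats::uniroot(function(e) expected_mean_force(pool, e) - target,
                   c(0, 100), tol = tol)$root
  }, numeric(1))
}
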