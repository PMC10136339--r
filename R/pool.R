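#' Motor neuron pool parameters
#'
#' Bundles the parameters that define a simulated motor neuron pool: how many
#' motor units it contains, the ranges of innervation number and twitch
#' properties across the pool, the recruitment range, and the rate-coding
#' strategy.
#'
#' The pool follows the classic size-ordered organisation: recruitment
#' thresholds, innervation numbers and peak twitch forces are exponentially
#' graded across the unit index so that most units are small and low-threshold,
#' while a few large high-threshold units dominate the upper force range.
#' Contraction time is tied to peak twitch force by a power law so that a
#' 100-fold twitch-force range coexists with a 3-fold contraction-time range.
#'
#' @param n_units number of motor units in the pool (default 150).
#' @param fibers_min,fibers_max innervation number of the smallest and largest
#'   unit (defaults 22 and 2137).
#' @param rte_max_fraction fraction of maximum excitation at which the last
#'   unit is recruited; 0.4 mimics small muscles where rate coding dominates,
#'   0.8 large muscles where recruitment operates over most of the force range.
#' @param mfr minimum firing rate at recruitment, Hz (default 8).
#' @param pfr_first,pfr_last peak firing rates (Hz) of the first- and
#'   last-recruited unit under the chosen `strategy`. With the defaults the
#'   onion-skin strategy gives the earliest unit 35 Hz and the latest 25 Hz;
#'   `reverse_onion_skin` gives the latest unit 35 Hz and the earliest 25 Hz.
#' @param strategy `"onion_skin"` or `"reverse_onion_skin"`.
#' @param twitch_p_min,twitch_p_max peak twitch force of the smallest/largest
#'   unit, arbitrary units (defaults 1 and 100).
#' @param twitch_t_max,twitch_t_min contraction time of the smallest/largest
#'   unit, ms (defaults 90 and 30).
#' @param isi_cv coefficient of variation of inter-spike intervals
#'   (dimensionless, default 0.2).
#' @param excitation_rate_gain firing-rate increase per percent excitation
#'   above a unit's recruitment threshold, Hz/%. The default `NULL` picks the
#'   gain at which the last-recruited unit just reaches its peak firing rate
#'   at 100% excitation, so maximum excitation means full rate coding of the
#'   whole pool and muscle force rises over the entire excitation range.
#'
#' @return An object of class `pool_params` (a validated list).
#' @seealso [build_pool()]
#' @export
pool_params <- function(n_units = 150L,
                        fibers_min = 22L, fibers_max = 2137L,
                        rte_max_fraction = 0.4,
                        mfr = 8,
                        pfr_first = NULL, pfr_last = NULL,
                        strategy = c("reverse_onion_skin", "onion_skin"),
                        twitch_p_min = 1, twitch_p_max = 100,
                        twitch_t_max = 90, twitch_t_min = 30,
                        isi_cv = 0.2,
                        excitation_rate_gain = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(pfr_first) || is.null(pfr_last)) {
    # highest PFR goes to the earliest unit under onion skin, latest otherwise
    if (strategy == "onion_skin") {
      pfr_first <- 35; pfr_last <- 25
    } else {
      pfr_first <- 25; pfr_last <- 35
    }
  }
  p <- list(
    n_units = as.integer(n_units),
    fibers_min = as.integer(fibers_min), fibers_max = as.integer(fibers_max),
    rte_max_fraction = rte_max_fraction,
    mfr = mfr, pfr_first = pfr_first, pfr_last = pfr_last,
    strategy = strategy,
    twitch_p_min = twitch_p_min, twitch_p_max = twitch_p_max,
    twitch_t_max = twitch_t_max, twitch_t_min = twitch_t_min,
    isi_cv = isi_cv,
    excitation_rate_gain = excitation_rate_gain
  )
  class(p) <- "pool_params"
  validate_pool_params(p)
  p
}

validate_pool_params <- function(p) {
  stopifnot(
    p$n_units >= 1L,
    p$fibers_min <= p$fibers_max,
    p$rte_max_fraction > 0, p$rte_max_fraction <= 1,
    p$mfr > 0,
    p$twitch_p_min > 0, p$twitch_p_max >= p$twitch_p_min,
    p$twitch_t_min > 0, p$twitch_t_max >= p$twitch_t_min,
    p$isi_cv >= 0
  )
  invisible(p)
}

#' Build a motor unit pool
#'
#' Constructs the per-unit arrays of a motor neuron pool from its parameters:
#' recruitment thresholds, innervation numbers, twitch force and contraction
#' time, and peak firing rates. All gradations are deterministic exponential
#' (or, for PFR, linear) interpolations across the unit index, so range
#' endpoints are exact and the pool is fully reproducible; randomness enters
#' the simulation only through discharge timing and territory geometry.
#'
#' Recruitment thresholds follow
#' `rte[i] = rte_max_fraction * 100 * exp(i * log(R) / n) / R` with a fixed
#' 100-fold range ratio `R`, so most units have low thresholds. Contraction
#' time is derived from peak twitch force by
#' `t_contract = twitch_t_max * p^(-log(3)/log(100))`, giving a 3-fold
#' contraction-time range over a 100-fold twitch-force range.
#'
#' @param params a [pool_params()] object.
#' @return An object of class `mu_pool`: a list with the parameter echo and
#'   per-unit vectors `rte` (% max excitation, strictly increasing),
#'   `n_fibers`, `p` (peak twitch force, au), `t_contract` (ms), `pfr` (Hz).
#' @examples
#' pool <- build_pool(pool_params())
#' range(pool$n_fibers)   # 22 2137
#' sum(pool$n_fibers)     # about 70,000 fibers
#' @export
build_pool <- function(params = pool_params()) {
  stopifnot(inherits(params, "pool_params"))
  if (params$n_units < 2L)
    stop("build_pool() needs at least 2 units for interpolation")
  n <- params$n_units
  i <- seq_len(n)
  R <- 100  # recruitment-threshold range ratio, matching the twitch range
  rte <- params$rte_max_fraction * 100 * exp(i * log(R) / n) / R
  n_fibers <- round(params$fibers_min *
    exp((i - 1) * log(params$fibers_max / params$fibers_min) / (n - 1)))
  p <- params$twitch_p_min *
    exp((i - 1) * log(params$twitch_p_max / params$twitch_p_min) / (n - 1))
  t_contract <- params$twitch_t_max *
    (params$twitch_p_min / p) ^ (log(params$twitch_t_max / params$twitch_t_min) /
                                   log(params$twitch_p_max / params$twitch_p_min))
  pfr <- params$pfr_first + (i - 1) * (params$pfr_last - params$pfr_first) / (n - 1)
  gain <- params$excitation_rate_gain
  if (is.null(gain)) {
    # last-recruited unit reaches its PFR exactly at full excitation
    gain <- (pfr[n] - params$mfr) / (100 - rte[n])
  }
  pool <- list(params = params, rte = rte, n_fibers = as.integer(n_fibers),
               p = p, t_contract = t_contract, pfr = pfr,
               mfr = params$mfr, excitation_rate_gain = gain)
  class(pool) <- "mu_pool"
  pool
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf("Motor unit pool: %d units, %d fibers total\n",
              x$params$n_units, sum(x$n_fibers)))
  cat(sprintf("  recruitment thresholds: %.2f-%.1f%% excitation\n",
              x$rte[1], x$rte[length(x$rte)]))
  cat(sprintf("  twitch force %g-%g au, contraction time %g-%g ms\n",
              x$p[1], x$p[length(x$p)],
              x$t_contract[1], x$t_contract[length(x$t_contract)]))
  cat(sprintf("  strategy %s: PFR %g Hz (first) to %g Hz (last), MFR %g Hz\n",
              x$params$strategy, x$pfr[1], x$pfr[length(x$pfr)], x$mfr))
  invisible(x)
}

#' Firing rate of a motor unit at a given excitation
#'
#' A unit is silent below its recruitment threshold; above it, its rate rises
#' linearly from the minimum firing rate with the pool's excitation-rate gain
#' until the unit's peak firing rate caps it.
#'
#' @param pool a `mu_pool`.
#' @param unit unit index (1-based) or vector of indices.
#' @param excitation excitatory drive, % of maximum (0-100).
#' @return Firing rate(s) in Hz.
#' @export
firing_rate <- function(pool, unit, excitation) {
  stopifnot(inherits(pool, "mu_pool"),
            excitation >= 0, excitation <= 100)
  if (any(unit < 1L | unit > pool$params$n_units))
    stop("unit index out of range")
  rte <- pool$rte[unit]
  rate <- pool$mfr + pool$excitation_rate_gain * (excitation - rte)
  rate <- pmin(rate, pool$pfr[unit])
  rate[excitation < rte] <- 0
  rate
}

#' Generate motor unit spike trains
#'
#' Simulates discharge times for every recruited unit at a constant excitatory
#' drive. Inter-spike intervals are drawn from a Gaussian with mean `1/rate`
#' and standard deviation `isi_cv/rate`, redrawn until positive (resampling
#' rather than clipping preserves the mean for the CVs of interest). The first
#' discharge of each unit is placed uniformly within one mean inter-spike
#' interval of the onset so units start out of phase.
#'
#' @param pool a `mu_pool`.
#' @param excitation excitatory drive, % of maximum.
#' @param duration length of the train, s.
#' @param isi_cv coefficient of variation of the inter-spike intervals;
#'   defaults to the pool parameter.
#' @param seed integer seed (required, for reproducibility).
#' @return An object of class `spike_trains`: list with `excitation`,
#'   `duration` and `spike_times`, a list of ordered numeric vectors (s), one
#'   per unit (empty for units below threshold).
#' @export
generate_spike_trains <- function(pool, excitation, duration,
                                  isi_cv = pool$params$isi_cv, seed) {
  stopifnot(inherits(pool, "mu_pool"), duration > 0, isi_cv >= 0)
  if (missing(seed)) stop("an explicit seed is required")
  n <- pool$params$n_units
  rates <- firing_rate(pool, seq_len(n), excitation)
  spike_times <- vector("list", n)
  with_local_seed(seed, {
    for (u in seq_len(n)) {
      r <- rates[u]
      if (r <= 0) { spike_times[[u]] <- numeric(0); next }
      mean_isi <- 1 / r
      # upper bound on spike count, generous for the CVs used here
      n_max <- ceiling(duration * r * 1.5) + 10L
      t0 <- stats::runif(1, 0, mean_isi)
      isi <- stats::rnorm(n_max, mean_isi, isi_cv * mean_isi)
      bad <- which(isi <= 0)
      while (length(bad)) {
        isi[bad] <- stats::rnorm(length(bad), mean_isi, isi_cv * mean_isi)
        bad <- bad[isi[bad] <= 0]
      }
      tt <- t0 + c(0, cumsum(isi))
      while (tt[length(tt)] <= duration) {  # rarely needed top-up
        more <- stats::rnorm(n_max, mean_isi, isi_cv * mean_isi)
        more <- more[more > 0]
        tt <- c(tt, tt[length(tt)] + cumsum(more))
      }
      spike_times[[u]] <- tt[tt <= duration]
    }
  })
  structure(list(excitation = excitation, duration = duration,
                 spike_times = spike_times),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  active <- sum(lengths(x$spike_times) > 0)
  cat(sprintf("Spike trains: %d active units of %d, excitation %g%%, %g s, %d discharges\n",
              active, length(x$spike_times), x$excitation, x$duration,
              sum(lengths(x$spike_times))))
  invisible(x)
}

#' Write / read a pool as a CSV table
#'
#' Serialises the per-unit arrays as a CSV (`unit, rte, n_fibers, p,
#' t_contract, pfr`) with a JSON parameter echo alongside.
#'
#' @param pool a `mu_pool`.
#' @param path CSV path; the JSON echo goes to `<path>.json`.
#' @return `write_pool_csv()` returns `path` invisibly; `read_pool_table()`
#'   returns a `data.frame`.
#' @export
write_pool_csv <- function(pool, path) {
  stopifnot(inherits(pool, "mu_pool"))
  df <- data.frame(unit = seq_len(pool$params$n_units), rte = pool$rte,
                   n_fibers = pool$n_fibers, p = pool$p,
                   t_contract = pool$t_contract, pfr = pool$pfr)
  data.table::fwrite(df, path)
  jsonlite::write_json(unclass(pool$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_table <- function(path) {
  as.data.frame(data.table::fread(path))
}
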