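#' Motor unit twitch kernel
#'
#' Force response of a motor unit to a single discharge: the impulse response
#' of a second-order critically damped system,
#' `f(t) = g * p * (t / t_contract) * exp(1 - t / t_contract)`,
#' which peaks at `g * p` when `t = t_contract`.
#'
#' @param p peak twitch force, au.
#' @param t_contract contraction time (time to peak), ms.
#' @param t time since the discharge, ms (scalar or vector, `t >= 0`).
#' @param g per-discharge gain (see [isi_gain()]); default 1.
#' @return Force at `t`, au.
#' @export
twitch_kernel <- function(p, t_contract, t, g = 1) {
  if (t_contract <= 0) stop("t_contract must be positive")
  stopifnot(all(t >= 0))
  g * p * (t / t_contract) * exp(1 - t / t_contract)
}

#' Nonlinear twitch gain from the preceding inter-spike interval
#'
#' As discharge rate rises and twitches fuse toward tetanus, the force
#' contributed per discharge no longer sums linearly. The gain applied to each
#' twitch depends on the ratio `u = t_contract / isi`: it is 1 for `u <= 0.4`
#' (slow, unfused firing) and follows the sigmoidal saturation
#' `S(u) = (1 - exp(-2 u^3)) / u`, normalised by `S(0.4)` so the gain is
#' continuous at the boundary, for `u > 0.4`.
#'
#' @param t_contract contraction time, ms.
#' @param isi preceding inter-spike interval, ms (same units as `t_contract`).
#' @return Gain (dimensionless, >= 1 in the fusion regime of this model).
#' @examples
#' isi_gain(90, 450)  # u = 0.2 -> 1
#' isi_gain(90, 90)   # u = 1   -> about 2.879
#' @export
isi_gain <- function(t_contract, isi) {
  stopifnot(all(isi > 0), t_contract > 0)
  u <- t_contract / isi
  S <- function(u) (1 - exp(-2 * u^3)) / u
  g <- ifelse(u <= 0.4, 1, S(u) / S(0.4))
  g
}

# samples a twitch kernel on the simulation grid; truncated where the
# amplitude falls below 1% of the peak (t = 8 * t_contract keeps the
# truncated tail under 0.5% of the kernel area)
twitch_kernel_samples <- function(p, t_contract, fs, span = 8) {
  n <- ceiling(span * (t_contract / 1000) * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  twitch_kernel(p, t_contract, t_ms)
}

#' Force trace of one motor unit
#'
#' Superposes one twitch kernel per discharge. Each discharge's gain is set by
#' the inter-spike interval that precedes it ([isi_gain()]); the first
#' discharge of a train has no preceding interval and uses gain 1.
#'
#' @param spikes ordered numeric vector of discharge times, s.
#' @param p peak twitch force, au.
#' @param t_contract contraction time, ms.
#' @param fs sampling rate, Hz.
#' @param duration trace length, s.
#' @return A `force_trace`: list with `samples` (au), `fs`, `duration`.
#' @export
unit_force <- function(spikes, p, t_contract, fs, duration) {
  stopifnot(fs > 0, duration > 0, !is.unsorted(spikes))
  n <- round(fs * duration)
  out <- numeric(n)
  if (length(spikes)) {
    kern <- twitch_kernel_samples(p, t_contract, fs)
    nk <- length(kern)
    gains <- c(1, if (length(spikes) > 1)
      isi_gain(t_contract, diff(spikes) * 1000))
    idx0 <- round(spikes * fs) + 1L
    for (j in seq_along(spikes)) {
      i0 <- idx0[j]
      if (i0 > n) next
      i1 <- min(n, i0 + nk - 1L)
      out[i0:i1] <- out[i0:i1] + gains[j] * kern[seq_len(i1 - i0 + 1L)]
    }
  }
  structure(list(samples = out, fs = fs, duration = duration),
            class = "force_trace")
}

#' Whole-muscle force
#'
#' Linear summation of the force outputs of all motor units.
#'
#' @param unit_traces list of `force_trace` objects with equal `fs` and
#'   `duration`.
#' @return A `force_trace` with the element-wise sum.
#' @export
total_force <- function(unit_traces) {
  stopifnot(length(unit_traces) >= 1)
  fs <- unit_traces[[1]]$fs; dur <- unit_traces[[1]]$duration
  n <- length(unit_traces[[1]]$samples)
  for (tr in unit_traces) {
    if (tr$fs != fs || length(tr$samples) != n)
      stop("force traces have mismatched sampling or length")
  }
  out <- Reduce(`+`, lapply(unit_traces, `[[`, "samples"))
  structure(list(samples = out, fs = fs, duration = dur),
            class = "force_trace")
}

#' Whole-muscle force from a spike-train set
#'
#' Computes the summed force of all units of a pool in one pass (equivalent
#' to [total_force()] over per-unit [unit_force()] traces, without
#' materialising 150 intermediate traces).
#'
#' @param pool a `mu_pool`.
#' @param trains a `spike_trains` object for the pool.
#' @param fs sampling rate, Hz.
#' @return A `force_trace`.
#' @export
muscle_force <- function(pool, trains, fs) {
  stopifnot(inherits(pool, "mu_pool"), inherits(trains, "spike_trains"))
  duration <- trains$duration
  n <- round(fs * duration)
  out <- numeric(n)
  for (u in seq_len(pool$params$n_units)) {
    sp <- trains$spike_times[[u]]
    if (!length(sp)) next
    tr <- unit_force(sp, pool$p[u], pool$t_contract[u], fs, duration)
    out <- out + tr$samples
  }
  structure(list(samples = out, fs = fs, duration = duration),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %g s at %g Hz, mean %.3g au, peak %.3g au\n",
              x$duration, x$fs, mean(x$samples), max(x$samples)))
  invisible(x)
}

#' Write a force trace as CSV
#'
#' Single-column CSV plus a JSON sidecar recording `fs` and units.
#' @param trace a `force_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(trace, path) {
  data.table::fwrite(data.frame(force_au = sprintf("%.17g", trace$samples)),
                     path, quote = FALSE)
  jsonlite::write_json(list(fs = trace$fs, duration = trace$duration,
                            units = "au"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
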