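#' Point-source surface potential
#'
#' Quasi-static potential of a single point current source in the homogeneous
#' anisotropic half-space, evaluated at a skin-plane electrode:
#' `phi = P / (2 * pi * sigma_x * sqrt(ka * (dx^2 + y^2) + dz^2))`,
#' with `dx`, `dz` the transverse/axial electrode-source offsets (mm) and `y`
#' the source depth (mm). This is the elementary term from which fiber action
#' potentials are assembled.
#'
#' @param p source strength (arbitrary units).
#' @param dx,y,dz source-to-electrode offsets, mm.
#' @param geometry a [muscle_geometry()].
#' @return Potential (arbitrary scale).
#' @export
point_source_potential <- function(p, dx, y, dz, geometry = muscle_geometry()) {
  r <- sqrt(geometry$ka * (dx^2 + y^2) + dz^2)
  if (any(r == 0)) stop("degenerate geometry: electrode coincides with a source")
  p / (2 * pi * geometry$sigma_x * r)
}

template_samples <- function(geometry, tripole, fs) {
  v <- geometry$conduction_velocity * 1000  # mm/s
  travel_t <- (geometry$fiber_half_length + max(tripole$offsets)) / v
  as.integer(ceiling(travel_t * fs)) + 2L
}

#' Single-fiber action potential at surface electrodes
#'
#' Time waveform of the potential generated by one fiber, modelled as two
#' mirrored travelling tripoles departing from the innervation zone at the
#' conduction velocity and extinguished at the fiber ends (the poles collapse
#' at the tendon, where charge balance makes the potential vanish).
#'
#' @param fiber_pos numeric `c(x, depth)` of the fiber, mm.
#' @param electrode_pos matrix or data frame with columns `x`, `z` (skin-plane
#'   coordinates, mm); a single electrode may be given as `c(x, z)`.
#' @param tripole a [tripole_spec()].
#' @param geometry a [muscle_geometry()].
#' @param fs sampling rate, Hz.
#' @param tilt fiber inclination, mm depth per mm z (default 0).
#' @return Matrix of waveforms, samples x electrodes (a plain vector when one
#'   electrode is given).
#' @export
sfap <- function(fiber_pos, electrode_pos, tripole = tripole_spec(),
                 geometry = muscle_geometry(), fs = 2000, tilt = 0) {
  el <- as_electrode_matrix(electrode_pos)
  check_fiber_depth(fiber_pos[2], tilt, geometry)
  n <- template_samples(geometry, tripole, fs)
  out <- muap_template_cpp(fiber_pos[1], fiber_pos[2], tilt,
                           el[, 1], el[, 2],
                           tripole$amplitudes, tripole$offsets,
                           geometry$innervation_zone_z,
                           geometry$fiber_half_length,
                           geometry$conduction_velocity * 1000,
                           geometry$ka, geometry$sigma_x, fs, n, 0.25)
  if (ncol(out) == 1L) drop(out) else out
}

as_electrode_matrix <- function(electrode_pos) {
  if (is.null(dim(electrode_pos))) {
    stopifnot(length(electrode_pos) == 2)
    matrix(electrode_pos, 1, 2)
  } else {
    el <- as.matrix(electrode_pos)
    if (!is.null(colnames(el)) && all(c("x", "z") %in% colnames(el)))
      el <- el[, c("x", "z"), drop = FALSE]
    stopifnot(ncol(el) == 2)
    storage.mode(el) <- "double"
    el
  }
}

check_fiber_depth <- function(depth, tilt, geometry) {
  if (any(depth - abs(tilt) * geometry$fiber_half_length <= 0))
    stop("fiber reaches the skin plane (zero source-electrode distance)")
  invisible(TRUE)
}

#' Motor unit action potential templates
#'
#' A motor unit action potential (MUAP) is the sum of the single-fiber action
#' potentials of all fibers in the unit's territory. `muap()` computes the
#' template of one unit; `muap_templates()` computes (and caches within the
#' returned list) templates for every unit of a placement at every electrode.
#'
#' @param fibers matrix with columns `x`, `depth` (mm), one row per fiber.
#' @param electrode_pos electrodes as in [sfap()].
#' @param tripole a [tripole_spec()].
#' @param geometry a [muscle_geometry()].
#' @param fs sampling rate, Hz.
#' @param tilt fiber inclination for the unit, mm/mm.
#' @return `muap()`: samples x electrodes matrix. `muap_templates()`: list of
#'   such matrices, one per unit.
#' @export
muap <- function(fibers, electrode_pos, tripole = tripole_spec(),
                 geometry = muscle_geometry(), fs = 2000, tilt = 0) {
  el <- as_electrode_matrix(electrode_pos)
  fibers <- as.matrix(fibers)
  check_fiber_depth(min(fibers[, 2]), tilt, geometry)
  n <- template_samples(geometry, tripole, fs)
  muap_template_cpp(fibers[, 1], fibers[, 2], rep_len(tilt, nrow(fibers)),
                    el[, 1], el[, 2],
                    tripole$amplitudes, tripole$offsets,
                    geometry$innervation_zone_z,
                    geometry$fiber_half_length,
                    geometry$conduction_velocity * 1000,
                    geometry$ka, geometry$sigma_x, fs, n, 0.25)
}

#' @rdname muap
#' @param placement a `pool_placement` from [place_pool()].
#' @export
muap_templates <- function(placement, electrode_pos,
                           tripole = tripole_spec(), fs = 2000) {
  stopifnot(inherits(placement, "pool_placement"))
  el <- as_electrode_matrix(electrode_pos)
  lapply(seq_along(placement$fibers), function(u)
    muap(placement$fibers[[u]], el, tripole, placement$geometry, fs,
         tilt = placement$tilt[u]))
}

#' Electrode grid layout
#'
#' Builds skin-plane electrode positions for a rows x cols grid. Rows advance
#' along the fiber direction (z), columns across the muscle (x); the grid is
#' centred on `center`.
#'
#' @param rows,cols grid dimensions.
#' @param pitch inter-electrode distance, mm (default 8).
#' @param center numeric `c(x, z)` of the grid centre, mm.
#' @return Data frame with columns `channel`, `row`, `col`, `x`, `z` and
#'   attribute `layout = c(rows, cols)`.
#' @export
electrode_grid <- function(rows = 13, cols = 6, pitch = 8, center = c(0, 0)) {
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  g <- g[order(g$col, g$row), ]
  out <- data.frame(channel = seq_len(nrow(g)), row = g$row, col = g$col,
                    x = center[1] + (g$col - (cols + 1) / 2) * pitch,
                    z = center[2] + (g$row - (rows + 1) / 2) * pitch)
  attr(out, "layout") <- c(rows = rows, cols = cols)
  attr(out, "pitch") <- pitch
  out
}

#' Synthesize a surface EMG recording
#'
#' Each channel is the sum over motor units of the unit's spike train
#' convolved with its MUAP template at that electrode (a sparse superposition
#' of MUAP trains). Spikes falling beyond the recording are dropped with a
#' warning.
#'
#' @param trains a `spike_trains` object.
#' @param templates list of MUAP template matrices from [muap_templates()]
#'   (samples x channels, one per unit).
#' @param fs sampling rate, Hz.
#' @param duration recording length, s (defaults to the train duration).
#' @param electrodes optional electrode data frame (kept as metadata).
#' @return An `emg_recording`: list with `signals` (samples x channels), `fs`,
#'   `duration`, `electrodes`.
#' @export
synthesize_emg <- function(trains, templates, fs, duration = trains$duration,
                           electrodes = NULL) {
  stopifnot(inherits(trains, "spike_trains"),
            length(templates) == length(trains$spike_times), fs > 0)
  n <- round(fs * duration)
  nc <- ncol(templates[[1]])
  signals <- matrix(0, n, nc)
  for (u in seq_along(templates)) {
    sp <- trains$spike_times[[u]]
    if (!length(sp)) next
    if (any(sp > duration)) {
      warning("spikes beyond the recording duration were dropped")
      sp <- sp[sp <= duration]
    }
    at <- as.integer(round(sp * fs) + 1L)
    at <- at[at <= n]
    if (!length(at)) next
    add_template_cpp(signals, templates[[u]], at, rep(1, length(at)))
  }
  structure(list(signals = signals, fs = fs, duration = duration,
                 electrodes = electrodes),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d channels x %d samples (%g s at %g Hz)\n",
              ncol(x$signals), nrow(x$signals), x$duration, x$fs))
  invisible(x)
}

#' Write / read an EMG recording as CSV
#'
#' Channels-in-columns CSV with a JSON sidecar holding the sampling rate and
#' electrode layout.
#'
#' @param rec an `emg_recording`.
#' @param path CSV path; sidecar goes to `<path>.json`.
#' @return `write_emg_csv()` returns `path` invisibly; `read_emg_csv()`
#'   returns an `emg_recording`.
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  # %.17g guarantees doubles survive the text round trip bit-exactly
  df <- as.data.frame(matrix(sprintf("%.17g", rec$signals),
                             nrow(rec$signals)))
  names(df) <- sprintf("ch%03d", seq_len(ncol(df)))
  data.table::fwrite(df, path, quote = FALSE)
  meta <- list(fs = rec$fs, duration = rec$duration,
               electrodes = rec$electrodes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  sig <- as.matrix(data.table::fread(path))
  dimnames(sig) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  electrodes <- if (!is.null(meta$electrodes))
    as.data.frame(meta$electrodes) else NULL
  structure(list(signals = sig, fs = meta$fs, duration = meta$duration,
                 electrodes = electrodes),
            class = "emg_recording")
}
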