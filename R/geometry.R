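#' Muscle and volume-conductor geometry
#'
#' The muscle is a cylinder of fibers running parallel to the z axis, covered
#' by a fat/skin layer that acts as a stand-off between the muscle boundary
#' and the recording plane. Coordinates: the skin surface is the plane y = 0,
#' depth increases into the tissue (y > 0), x runs transversally, z along the
#' fibers. The medium is homogeneous but anisotropic, with longitudinal
#' conductivity `sigma_z` and transverse conductivity `sigma_x`
#' (`ka = sigma_z / sigma_x`).
#'
#' @param muscle_diameter muscle diameter, mm (default 24).
#' @param fat_skin_thickness fat plus skin layer thickness, mm (default 3).
#' @param sigma_z,sigma_x longitudinal / transverse conductivity, S/m
#'   (defaults 0.33 and 0.06).
#' @param fiber_half_length fiber semi-length from the innervation zone to the
#'   tendon, mm (default 60).
#' @param conduction_velocity action-potential conduction velocity, m/s
#'   (default 4).
#' @param innervation_zone_z axial position of the innervation zone, mm
#'   (default 0).
#' @return A `muscle_geometry` object (validated list; includes the derived
#'   anisotropy ratio `ka`).
#' @export
muscle_geometry <- function(muscle_diameter = 24, fat_skin_thickness = 3,
                            sigma_z = 0.33, sigma_x = 0.06,
                            fiber_half_length = 60, conduction_velocity = 4,
                            innervation_zone_z = 0) {
  stopifnot(muscle_diameter > 0, fat_skin_thickness >= 0,
            sigma_z > 0, sigma_x > 0,
            fiber_half_length > 0, conduction_velocity > 0)
  g <- list(muscle_diameter = muscle_diameter,
            fat_skin_thickness = fat_skin_thickness,
            sigma_z = sigma_z, sigma_x = sigma_x, ka = sigma_z / sigma_x,
            fiber_half_length = fiber_half_length,
            conduction_velocity = conduction_velocity,
            innervation_zone_z = innervation_zone_z)
  class(g) <- "muscle_geometry"
  g
}

#' Travelling tripole source specification
#'
#' A fiber action potential is represented by three balanced point current
#' sources travelling along the fiber; two mirrored triplets propagate in +z
#' and -z from the innervation zone, so six poles describe one fiber. Charge
#' balance (amplitudes summing to zero) is enforced at construction; it makes
#' the surface potential vanish exactly when the poles are collapsed at the
#' innervation zone (before generation) and at the fiber end (after
#' extinction).
#'
#' @param amplitudes three signed source strengths for one triplet, summing to
#'   zero. Default `c(1, -2.6, 1.6)` (leading, main sink, trailing).
#' @param spacing inter-pole spacing, mm (default 2).
#' @param scale overall multiplicative scale (default 1).
#' @return A `tripole_spec` with `amplitudes` and `offsets` (mm behind the
#'   leading pole).
#' @export
tripole_spec <- function(amplitudes = c(1, -2.6, 1.6), spacing = 2, scale = 1) {
  stopifnot(length(amplitudes) == 3, spacing > 0)
  if (abs(sum(amplitudes)) > 1e-9 * max(abs(amplitudes)))
    stop("tripole amplitudes must sum to zero (charge balance)")
  s <- list(amplitudes = amplitudes * scale,
            offsets = c(0, spacing, 2 * spacing),
            spacing = spacing)
  class(s) <- "tripole_spec"
  s
}

#' Assign motor unit territory depths under a depth-distribution condition
#'
#' Draws a territory centre for every unit in the cross-section. The depth of
#' a unit (mm from the skin surface) is a linear trend in its peak twitch
#' force plus Gaussian jitter, redrawn when it falls outside the muscle:
#' `depth = depth_center + slope * (p - mean(p)) + N(0, jitter_sd)`.
#' The three conditions set the slope, in mm of depth per au of twitch force:
#' `superficial` -0.13 (large, high-threshold units lie shallow, spanning
#' about 13 mm of stratification over the 100-fold twitch range), `random` 0,
#' `deep` +0.12. The fitted OLS regression of depth on twitch force recovers
#' these magnitudes. Transverse centres are uniform across the chord of the
#' cross-section at the drawn depth.
#'
#' @param pool a `mu_pool`.
#' @param condition `"superficial"`, `"random"` or `"deep"`.
#' @param geometry a [muscle_geometry()].
#' @param jitter_sd SD of the depth jitter, mm (default 2).
#' @param seed integer seed.
#' @param depth_slope optional override of the condition's size-depth slope,
#'   mm/au.
#' @param depth_center mean territory depth, mm from the skin (default
#'   mid-muscle).
#' @return A `unit_placement` data frame: columns `unit`, `x` (mm), `depth`
#'   (mm from the skin surface), `depth_norm` (0-1 across the muscle),
#'   `radius` (territory radius, mm), plus attributes `condition` and
#'   `fitted_slope` (OLS slope of depth on twitch force, mm/au).
#' @export
assign_depths <- function(pool, condition = c("superficial", "random", "deep"),
                          geometry = muscle_geometry(), jitter_sd = 2,
                          seed, depth_slope = NULL, depth_center = NULL) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(inherits(pool, "mu_pool"), inherits(geometry, "muscle_geometry"))
  slope <- if (!is.null(depth_slope)) depth_slope else
    switch(condition, superficial = -0.13, random = 0, deep = 0.12)
  n <- pool$params$n_units
  r_m <- geometry$muscle_diameter / 2
  fat <- geometry$fat_skin_thickness
  if (is.null(depth_center)) depth_center <- fat + r_m
  lo <- fat + 0.5; hi <- fat + geometry$muscle_diameter - 0.5
  with_local_seed(seed, {
    centre <- depth_center + slope * (pool$p - mean(pool$p))
    d <- centre + stats::rnorm(n, 0, jitter_sd)
    bad <- which(d <= lo | d >= hi)
    tries <- 0L
    while (length(bad)) {
      d[bad] <- centre[bad] + stats::rnorm(length(bad), 0, jitter_sd)
      bad <- bad[d[bad] <= lo | d[bad] >= hi]
      tries <- tries + 1L
      if (tries > 200L) { d[bad] <- pmin(pmax(centre[bad], lo), hi); break }
    }
    # transverse position uniform on the chord at the drawn depth
    y_rel <- d - (fat + r_m)                 # distance from cylinder axis
    half_chord <- sqrt(pmax(r_m^2 - y_rel^2, 0))
    x <- stats::runif(n, -half_chord, half_chord)
  })
  radius <- territory_radius(pool$n_fibers)
  fit <- stats::lm.fit(cbind(1, pool$p), d)
  out <- data.frame(unit = seq_len(n), x = x, depth = d,
                    depth_norm = (d - fat) / geometry$muscle_diameter,
                    radius = radius)
  attr(out, "condition") <- condition
  attr(out, "fitted_slope") <- unname(fit$coefficients[2])
  class(out) <- c("unit_placement", "data.frame")
  out
}

# territory radius from innervation number at fixed areal fiber density
territory_radius <- function(n_fibers, density = 20) {
  sqrt(n_fibers / (pi * density))
}

#' Place the fibers of one motor unit territory
#'
#' Fibers are uniform in a disc centred on the unit's territory centre, with
#' radius set by the innervation number at a fixed areal density
#' (`radius = sqrt(n_fibers / (pi * density))`), intersected with the muscle
#' cross-section by rejection sampling.
#'
#' @param center numeric `c(x, depth)` of the territory centre, mm (depth from
#'   the skin surface).
#' @param n_fibers number of fibers to place.
#' @param geometry a [muscle_geometry()].
#' @param density areal fiber density, fibers/mm^2 (default 20).
#' @param seed integer seed.
#' @return Matrix with columns `x`, `depth` (mm), one row per fiber.
#' @export
place_fibers <- function(center, n_fibers, geometry = muscle_geometry(),
                         density = 20, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(length(center) == 2, n_fibers >= 1)
  r_m <- geometry$muscle_diameter / 2
  yc_muscle <- geometry$fat_skin_thickness + r_m  # cylinder axis depth
  if ((center[1])^2 + (center[2] - yc_muscle)^2 >= r_m^2)
    stop("territory centre lies outside the muscle cross-section")
  rt <- territory_radius(n_fibers, density)
  if (rt > r_m) {
    warning("territory radius exceeds the muscle radius; clipping")
    rt <- r_m
  }
  out <- matrix(NA_real_, n_fibers, 2, dimnames = list(NULL, c("x", "depth")))
  with_local_seed(seed, {
    got <- 0L
    while (got < n_fibers) {
      m <- max(2L * (n_fibers - got), 64L)
      ang <- stats::runif(m, 0, 2 * pi)
      rad <- rt * sqrt(stats::runif(m))
      x <- center[1] + rad * cos(ang)
      y <- center[2] + rad * sin(ang)
      keep <- (x^2 + (y - yc_muscle)^2) < r_m^2
      k <- min(sum(keep), n_fibers - got)
      if (k > 0) {
        idx <- which(keep)[seq_len(k)]
        out[got + seq_len(k), 1] <- x[idx]
        out[got + seq_len(k), 2] <- y[idx]
        got <- got + k
      }
    }
  })
  out
}

#' Build the full fiber placement for a pool
#'
#' Combines [assign_depths()] and [place_fibers()] for every unit, optionally
#' tilting fibers so their depth varies along the fiber axis (see
#' `depth_tilt`). Tilts are clamped so no fiber rises above `min_depth` within
#' its half-length.
#'
#' @param pool a `mu_pool`.
#' @param condition depth-distribution condition, see [assign_depths()].
#' @param geometry a [muscle_geometry()].
#' @param seed integer seed; fiber placement derives per-unit seeds from it.
#' @param depth_tilt per-unit fiber inclination, mm depth per mm along z
#'   (positive: shallower proximally, i.e. toward -z). Scalar or length
#'   `n_units`; default 0 (fibers parallel to the skin).
#' @param jitter_sd,depth_slope passed to [assign_depths()].
#' @param density areal fiber density, fibers/mm^2.
#' @param min_depth minimum fiber depth allowed anywhere along the fiber, mm.
#' @return A `pool_placement`: list with `centers` (the `unit_placement`),
#'   `fibers` (list of per-unit fiber matrices), `tilt` (per-unit), `geometry`.
#' @export
place_pool <- function(pool, condition = "random", geometry = muscle_geometry(),
                       seed, depth_tilt = 0, jitter_sd = 2,
                       depth_slope = NULL, density = 20, min_depth = 0.5) {
  if (missing(seed)) stop("an explicit seed is required")
  centers <- assign_depths(pool, condition, geometry, jitter_sd,
                           seed = derive_seed(seed, 1L),
                           depth_slope = depth_slope)
  n <- pool$params$n_units
  tilt <- rep_len(depth_tilt, n)
  fibers <- vector("list", n)
  for (u in seq_len(n)) {
    fibers[[u]] <- place_fibers(c(centers$x[u], centers$depth[u]),
                                pool$n_fibers[u], geometry, density,
                                seed = derive_seed(seed, 100L + u))
    # a tilted fiber must stay below the skin over its whole course
    max_tilt <- max(0, (min(fibers[[u]][, 2]) - min_depth) /
                      geometry$fiber_half_length)
    tilt[u] <- sign(tilt[u]) * min(abs(tilt[u]), max_tilt)
  }
  structure(list(centers = centers, fibers = fibers, tilt = tilt,
                 geometry = geometry, condition = attr(centers, "condition")),
            class = "pool_placement")
}

#' @export
print.pool_placement <- function(x, ...) {
  cat(sprintf("Pool placement: %d units (%s condition), fitted size-depth slope %.3f\n",
              nrow(x$centers), x$condition, attr(x$centers, "fitted_slope")))
  invisible(x)
}
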