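#' Root-mean-square amplitude
#'
#' The EMG amplitude measure used throughout: `sqrt(mean(x^2))`.
#'
#' @param x non-empty numeric vector (an EMG segment).
#' @return RMS amplitude.
#' @export
emg_rms <- function(x) {
  if (!length(x)) stop("empty segment")
  sqrt(mean(x^2))
}

#' Level series of force and EMG amplitude
#'
#' Pairs the mean force and per-channel RMS measured at each contraction
#' level, the input to the log-log regression.
#'
#' @param force numeric vector of mean force per level (au or normalized),
#'   strictly positive.
#' @param rms matrix of RMS values, levels x channels (a vector is treated as
#'   one channel).
#' @param levels optional level labels (% excitation or %MVC).
#' @return A `level_series`.
#' @export
level_series <- function(force, rms, levels = NULL) {
  rms <- as.matrix(rms)
  stopifnot(length(force) == nrow(rms), all(force > 0), all(rms > 0))
  if (length(force) < 3) stop("at least 3 levels are required for regression")
  structure(list(force = force, rms = rms,
                 levels = levels %||% seq_along(force)),
            class = "level_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a level series to its maximum level
#'
#' Divides force and each channel's RMS by their values at the highest-force
#' level. The log-log slope b is invariant under this rescaling (it shifts
#' only the intercept), so normalization serves comparability of intercepts
#' across sessions, not the slope itself.
#'
#' @param series a [level_series()].
#' @return A normalized `level_series`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "level_series"))
  imax <- which.max(series$force)
  level_series(series$force / series$force[imax],
               sweep(series$rms, 2, series$rms[imax, ], "/"),
               series$levels)
}

#' Fit the log-transformed EMG-force relation
#'
#' Ordinary least squares fit of `ln Y = b ln X + ln a`, with X the force and
#' Y the RMS amplitude. The slope b characterises the shape of the raw
#' relation `Y = a X^b`: b = 1 is linear, b > 1 faster than linear, b < 1
#' slower than linear.
#'
#' @param series a [level_series()], or a positive numeric vector of forces.
#' @param channel channel index of the RMS column to fit (default 1). When
#'   `series` is a numeric vector, `channel` must be the matching Y vector.
#' @return A `slope_fit`: list with `b`, `ln_a`, `r_squared`, `n_levels`.
#' @examples
#' x <- seq(0.1, 1, length.out = 10)
#' fit_loglog(x, 2 * x^1.5)  # b = 1.5, ln_a = log(2)
#' @export
fit_loglog <- function(series, channel = 1) {
  if (inherits(series, "level_series")) {
    x <- series$force
    y <- series$rms[, channel]
  } else {
    x <- series
    y <- channel
  }
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(x <= 0) || any(y <= 0))
    stop("log-log regression requires strictly positive X and Y")
  lx <- log(x); ly <- log(y)
  if (max(lx) - min(lx) < 1e-12) stop("degenerate X: all levels equal")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  b <- unname(fit$coefficients[2])
  ln_a <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(b = b, ln_a = ln_a, r_squared = min(max(r2, 0), 1),
                 n_levels = length(x)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("log-log EMG-force fit: b = %.4f, ln a = %.4f, r^2 = %.4f (%d levels)\n",
              x$b, x$ln_a, x$r_squared, x$n_levels))
  invisible(x)
}

#' Per-channel slope map over an electrode grid
#'
#' Fits the log-log EMG-force relation independently on every channel of a
#' grid session (all channels share the force vector of the same
#' contractions) and arranges the slopes b in grid coordinates. Channels
#' whose fit fails are marked missing (`NA`) rather than aborting the map.
#'
#' @param series a [level_series()] whose RMS columns are the grid channels.
#' @param electrodes electrode data frame from [electrode_grid()] (columns
#'   `channel`, `row`, `col`). When `NULL`, channels are laid out in a single
#'   row.
#' @return A `slope_map`: matrix rows x cols of b values with attribute
#'   `fits` (list of `slope_fit` per channel, `NULL` where failed).
#' @export
slope_map <- function(series, electrodes = NULL) {
  stopifnot(inherits(series, "level_series"))
  nc <- ncol(series$rms)
  fits <- vector("list", nc)
  b <- rep(NA_real_, nc)
  for (ch in seq_len(nc)) {
    f <- tryCatch(fit_loglog(series, ch), error = function(e) NULL)
    fits[[ch]] <- f
    if (!is.null(f)) b[ch] <- f$b
  }
  if (is.null(electrodes)) {
    map <- matrix(b, nrow = 1)
  } else {
    stopifnot(nrow(electrodes) == nc)
    nr <- max(electrodes$row); ncol_g <- max(electrodes$col)
    map <- matrix(NA_real_, nr, ncol_g)
    # RMS column i belongs to the electrode described by row i
    map[cbind(electrodes$row, electrodes$col)] <- b
  }
  structure(map, class = c("slope_map", "matrix"), fits = fits)
}

#' @export
print.slope_map <- function(x, ...) {
  cat(sprintf("Slope map: %d x %d grid, %d fitted channels\n",
              nrow(x), ncol(x), sum(!is.na(x))))
  m <- unclass(x); attr(m, "fits") <- NULL
  print(round(m, 3))
  invisible(x)
}

#' Named regions of an electrode grid
#'
#' Row/column index sets used for regional slope comparisons. Defaults:
#' proximal rows 3-4, distal rows 10-11, lateral columns 1-2, medial columns
#' 5-6 (1-based grid indices).
#'
#' @param proximal_rows,distal_rows,lateral_cols,medial_cols integer index
#'   vectors.
#' @return A `region_spec` list of regions, each with `rows` and/or `cols`.
#' @export
region_spec <- function(proximal_rows = c(3, 4), distal_rows = c(10, 11),
                        lateral_cols = c(1, 2), medial_cols = c(5, 6)) {
  structure(list(proximal = list(rows = proximal_rows),
                 distal = list(rows = distal_rows),
                 lateral = list(cols = lateral_cols),
                 medial = list(cols = medial_cols)),
            class = "region_spec")
}

#' Mean slope within a grid region
#'
#' Averages the non-missing b values of the channels selected by a region
#' (all columns of the given rows, or all rows of the given columns).
#'
#' @param map a [slope_map()].
#' @param region one element of a [region_spec()] (a list with `rows` and/or
#'   `cols`), or a name in `regions`.
#' @param regions a [region_spec()] used when `region` is a name.
#' @return Mean b of the region.
#' @export
region_mean <- function(map, region, regions = region_spec()) {
  stopifnot(inherits(map, "slope_map"))
  if (is.character(region)) region <- regions[[region]]
  rows <- region$rows %||% seq_len(nrow(map))
  cols <- region$cols %||% seq_len(ncol(map))
  if (any(rows > nrow(map)) || any(cols > ncol(map)))
    stop("region indices exceed the grid")
  vals <- map[rows, cols, drop = FALSE]
  if (all(is.na(vals))) stop("region contains no fitted channels")
  mean(vals, na.rm = TRUE)
}

#' Write a slope map as CSV
#'
#' @param map a [slope_map()].
#' @param path CSV path (rows x cols, no header index).
#' @return `path`, invisibly.
#' @export
write_slope_map_csv <- function(map, path) {
  df <- as.data.frame(unclass(map))
  names(df) <- sprintf("col%d", seq_len(ncol(df)))
  data.table::fwrite(df, path)
  invisible(path)
}
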