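#' Construct a trajectory
#'
#' Centroid positions of the fish in arena coordinates over time.
#'
#' @param times_s Strictly increasing sample times (s).
#' @param x,y Positions (mm).
#' @param fps Frame rate.
#' @return A \code{trajectory} data.frame with attribute \code{fps}.
#' @export
trajectory <- function(times_s, x, y, fps) {
  stopifnot(length(times_s) == length(x), length(x) == length(y),
            all(diff(times_s) > 0), fps > 0)
  structure(data.frame(times_s = times_s, x = x, y = y),
            fps = fps, class = c("trajectory", "data.frame"))
}

#' Tortuosity of a midline
#'
#' \deqn{\tau = \frac{L - d}{L}}
#' where \eqn{L} is the body arc length and \eqn{d} the head-to-tail
#' distance: 0 for a perfectly straight body, 1 when head and tail touch.
#' Invariant to rotation, translation and scale; clipped into [0, 1] against
#' floating-point round-off.
#'
#' @param m A \code{midline} or two-column coordinate matrix (head first).
#' @return Tortuosity in [0, 1].
#' @export
tortuosity <- function(m) {
  pts <- unclass(as.matrix(m))
  L <- arc_length(pts)
  if (L <= 0) stop("invalid-midline: zero arc length")
  d <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  min(1, max(0, (L - d) / L))
}

#' Speed and thrust-velocity series of a trajectory
#'
#' Speed from centred-difference displacements; thrust velocity is the
#' velocity component along the smoothed heading (the direction of travel),
#' so backwards drift counts negative. Summaries of these series are
#' reported as medians.
#'
#' @param traj A \code{trajectory} (>= 3 samples).
#' @param heading_window Centred moving-average window (samples, odd) used
#'   to smooth the heading.
#' @return data.frame: \code{times_s}, \code{speed} (mm/s), \code{thrust}
#'   (mm/s along heading).
#' @export
velocity_series <- function(traj, heading_window = 5) {
  stopifnot(nrow(traj) >= 3)
  if (any(diff(traj$times_s) <= 0)) stop("non-monotone times")
  fps <- attr(traj, "fps")
  n <- nrow(traj)
  cd <- function(v) c(v[2] - v[1], (v[-(1:2)] - v[-((n - 1):n)]) / 2,
                      v[n] - v[n - 1]) * fps
  vx <- cd(traj$x); vy <- cd(traj$y)
  speed <- sqrt(vx^2 + vy^2)
  hx <- smooth_ma(vx, heading_window)
  hy <- smooth_ma(vy, heading_window)
  hn <- sqrt(hx^2 + hy^2)
  hx <- ifelse(hn > 0, hx / hn, 0); hy <- ifelse(hn > 0, hy / hn, 0)
  thrust <- vx * hx + vy * hy
  data.frame(times_s = traj$times_s, speed = speed, thrust = thrust)
}

smooth_ma <- function(v, w) {
  w <- min(w, length(v))
  if (w <= 1) return(v)
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2)) ->
    out
  out[is.na(out)] <- v[is.na(out)]
  out
}

#' Maximum bending angle of a midline
#'
#' Angle between the chord of the rostral third and the chord of the caudal
#' third of the body — a coarse, tracker-robust measure of how strongly the
#' body is bent.
#'
#' @param m A \code{midline} (>= 3 points).
#' @param rostral_window,caudal_window Arc-length windows (fractions of
#'   point count) defining the two chords.
#' @return Unsigned angle in radians in [0, pi].
#' @export
max_bending_angle <- function(m, rostral_window = c(0, 1 / 3),
                              caudal_window = c(2 / 3, 1)) {
  pts <- unclass(as.matrix(m))
  n <- nrow(pts)
  stopifnot(n >= 3)
  idx <- function(w) {
    i <- unique(round(1 + w * (n - 1)))
    if (diff(i) < 1) stop("degenerate chord window")
    i
  }
  ir <- idx(rostral_window); ic <- idx(caudal_window)
  v1 <- pts[ir[2], ] - pts[ir[1], ]
  v2 <- pts[ic[2], ] - pts[ic[1], ]
  if (sum(v1^2) == 0 || sum(v2^2) == 0) stop("degenerate chord")
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2)))))
  ang
}

#' Per-frame bending-angle series of a midline sequence
#'
#' @param seq A \code{midline_seq}.
#' @inheritParams max_bending_angle
#' @return Numeric vector of bending angles (rad), one per frame.
#' @export
bending_angle_series <- function(seq, rostral_window = c(0, 1 / 3),
                                 caudal_window = c(2 / 3, 1)) {
  vapply(seq$midlines, max_bending_angle, numeric(1),
         rostral_window = rostral_window, caudal_window = caudal_window)
}

#' Occupancy heat map of an arena trajectory
#'
#' 2-D position histogram over the arena, converted to percentages that sum
#' to 100. Samples outside the arena are clipped to the boundary with a
#' warning, so mass is always conserved.
#'
#' @param traj A \code{trajectory}.
#' @param arena An \code{arena_spec}.
#' @param n_bins Bins per axis, \code{c(nx, ny)} or a scalar.
#' @return An \code{occupancy_map}: list with \code{x_edges},
#'   \code{y_edges}, \code{pct} (matrix [nx, ny], percentages).
#' @export
occupancy_map <- function(traj, arena = arena_spec(), n_bins = c(30, 10)) {
  if (nrow(traj) == 0) stop("empty trajectory")
  if (length(n_bins) == 1) n_bins <- rep(n_bins, 2)
  x <- traj$x; y <- traj$y
  if (any(x < 0 | x > arena$width_mm | y < 0 | y > arena$height_mm)) {
    warning("positions outside arena clipped to boundary")
    x <- pmin(arena$width_mm, pmax(0, x))
    y <- pmin(arena$height_mm, pmax(0, y))
  }
  xe <- seq(0, arena$width_mm, length.out = n_bins[1] + 1)
  ye <- seq(0, arena$height_mm, length.out = n_bins[2] + 1)
  ix <- pmin(n_bins[1], findInterval(x, xe, rightmost.closed = TRUE))
  iy <- pmin(n_bins[2], findInterval(y, ye, rightmost.closed = TRUE))
  counts <- matrix(0, n_bins[1], n_bins[2])
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  pct <- 100 * counts / sum(counts)
  structure(list(x_edges = xe, y_edges = ye, pct = pct),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("Occupancy map: %d x %d bins, max cell %.2f%%\n",
              nrow(x$pct), ncol(x$pct), max(x$pct)))
  invisible(x)
}

#' Fraction of time spent in the arena's centre band
#'
#' Fraction of samples whose lateral (y) coordinate lies within the central
#' band of width \code{centre_band_frac * height_mm} around the arena's
#' longitudinal centre line.
#'
#' @param traj A \code{trajectory}.
#' @param arena An \code{arena_spec}.
#' @return Fraction in [0, 1].
#' @export
centre_occupancy <- function(traj, arena = arena_spec()) {
  half_band <- arena$centre_band_frac * arena$height_mm / 2
  cy <- arena$height_mm / 2
  mean(abs(traj$y - cy) <= half_band)
}

#' Stimulus-aligned escape time series with bootstrap median band
#'
#' Per individual, computes tortuosity per frame and speed, re-zeroes time
#' at the stimulus, resamples all individuals onto a common time grid, and
#' summarizes across individuals as the median with a percentile-bootstrap
#' confidence band (see [bootstrap_median_band()]).
#'
#' @param seqs List of \code{midline_seq}, one per individual.
#' @param trajs Optional list of \code{trajectory} (defaults to the midline
#'   centroid path of each sequence).
#' @param stim_times Stimulus time (s) per individual (recycled if scalar).
#' @param grid_hz Common time grid rate; defaults to the lowest fps.
#' @param level Confidence level (percent).
#' @param n_boot,seed Bootstrap settings.
#' @return List with \code{time_s} (relative to stimulus), \code{tortuosity}
#'   and \code{speed}, each a list \code{median, lower, upper, series}
#'   (matrix individual x time).
#' @export
escape_timeseries <- function(seqs, trajs = NULL, stim_times, grid_hz = NULL,
                              level = 95, n_boot = 1000, seed = 1) {
  n_ind <- length(seqs)
  stim_times <- rep_len(stim_times, n_ind)
  fps_all <- vapply(seqs, function(s) s$fps, numeric(1))
  if (is.null(grid_hz)) {
    grid_hz <- min(fps_all)
    if (length(unique(fps_all)) > 1)
      message("mixed frame rates; resampling all individuals to ",
              round(grid_hz, 2), " Hz")
  }
  rel_ranges <- vapply(seq_len(n_ind), function(i) {
    nt <- length(seqs[[i]]$midlines)
    c(-stim_times[i], (nt - 1) / fps_all[i] - stim_times[i])
  }, numeric(2))
  lo <- max(rel_ranges[1, ]); hi <- min(rel_ranges[2, ])
  stopifnot(lo <= 0, hi >= 0)  # stimulus within every record
  grid <- seq(lo, hi, by = 1 / grid_hz)
  tort <- speed <- matrix(NA_real_, n_ind, length(grid))
  for (i in seq_len(n_ind)) {
    s <- seqs[[i]]
    t_rel <- (seq_along(s$midlines) - 1) / s$fps - stim_times[i]
    tv <- vapply(s$midlines, tortuosity, numeric(1))
    tort[i, ] <- stats::approx(t_rel, tv, xout = grid, rule = 2)$y
    tr <- if (!is.null(trajs)) trajs[[i]] else {
      cen <- t(vapply(s$midlines, colMeans, numeric(2)))
      trajectory((seq_along(s$midlines) - 1) / s$fps, cen[, 1], cen[, 2],
                 s$fps)
    }
    vs <- velocity_series(tr)
    speed[i, ] <- stats::approx(vs$times_s - stim_times[i], vs$speed,
                                xout = grid, rule = 2)$y
  }
  band <- function(M, s_off) bootstrap_median_band(M, level = level,
                                                   n_boot = n_boot,
                                                   seed = seed + s_off)
  list(time_s = grid,
       tortuosity = c(band(tort, 0), list(series = tort)),
       speed = c(band(speed, 1), list(series = speed)))
}
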