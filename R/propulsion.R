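#' Propulsion model configuration
#'
#' Physical constants for the elongated-body thrust model and the opposing
#' quadratic body drag. Defaults describe an adult zebrafish (~30 mm) in
#' water; they are deliberately coarse — the model is used for ordinal
#' comparisons between kinematic conditions, not absolute speed prediction.
#'
#' @param water_density kg/m^3.
#' @param tail_span_mm Tail-tip section depth (mm); sets the added mass per
#'   unit length \eqn{m_a = \rho \pi (span/2)^2}.
#' @param drag_coeff Dimensionless drag coefficient on the wetted area.
#' @param wetted_area_mm2 Wetted surface area (mm^2).
#' @param speed_bracket_bl_s Search interval for the steady speed (BL/s),
#'   lower bound 0.
#' @return A \code{propulsion_config} list.
#' @export
propulsion_config <- function(water_density = 1000,
                              tail_span_mm = 3.5,
                              drag_coeff = 0.01,
                              wetted_area_mm2 = 300,
                              speed_bracket_bl_s = c(0, 30)) {
  stopifnot(water_density > 0, tail_span_mm > 0, drag_coeff > 0,
            wetted_area_mm2 > 0, length(speed_bracket_bl_s) == 2,
            speed_bracket_bl_s[1] == 0, speed_bracket_bl_s[2] > 0)
  structure(list(water_density = water_density, tail_span_mm = tail_span_mm,
                 drag_coeff = drag_coeff, wetted_area_mm2 = wetted_area_mm2,
                 speed_bracket_bl_s = speed_bracket_bl_s),
            class = "propulsion_config")
}

#' Free-swimming (recoil-corrected) body frame
#'
#' A swimming fish is force- and torque-free in the lateral direction, so
#' prescribed body bending is accompanied by a rigid recoil of the whole
#' body that keeps net lateral momentum and angular momentum at zero.
#' This function applies the position-level (small-recoil) form of that
#' constraint frame by frame: each midline is translated so its
#' mass-weighted centroid sits at the origin and rotated so its
#' mass-weighted principal axis lies along +x (head towards -x side first
#' point). The correction matters for where bending is effective: without
#' it, a bend placed rostrally always moves the tail more (longer lever
#' arm); with it, rostral bends are discounted because they swing more
#' body mass and therefore provoke more counter-recoil. For a localized
#' bend of angle \eqn{\theta} at arc-length fraction \eqn{s_0} on a
#' uniform-mass body, the recoil-corrected tail displacement is
#' \eqn{\theta L s_0^2 (1 - s_0)}, maximal at \eqn{s_0 = 2/3} — caudal
#' placements win.
#'
#' @param seq A \code{midline_seq}.
#' @param mass Optional per-point mass weights (default uniform mass per
#'   unit length).
#' @return A \code{midline_seq} in the recoil-corrected body frame.
#' @export
recoil_frame <- function(seq, mass = NULL) {
  stopifnot(inherits(seq, "midline_seq"))
  np <- nrow(seq$midlines[[1]])
  if (is.null(mass)) mass <- rep(1, np)
  stopifnot(length(mass) == np, all(mass > 0))
  out <- lapply(seq$midlines, function(P) {
    cm <- colSums(P * mass) / sum(mass)
    Q <- sweep(P, 2, cm)
    Sxx <- sum(mass * Q[, 1]^2)
    Syy <- sum(mass * Q[, 2]^2)
    Sxy <- sum(mass * Q[, 1] * Q[, 2])
    phi <- 0.5 * atan2(2 * Sxy, Sxx - Syy)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    Q2 <- Q %*% R
    if (Q2[np, 1] < Q2[1, 1]) Q2 <- -Q2   # head-to-tail along +x
    Q2
  })
  midline_seq(out, fps = seq$fps, units = seq$units,
              scale_px_per_mm = seq$scale_px_per_mm)
}

#' Tail-tip kinematics of a midline sequence
#'
#' Extracts the elongated-body-theory inputs at the tail tip: lateral
#' displacement \code{h(t)} from the mean swimming axis, lateral velocity
#' \code{hdot(t)} by centred finite differences, and the tangent slope
#' \code{hprime(t)} of the last body segment relative to the axis. With
#' \code{recoil = TRUE} (the default) the sequence is first moved into the
#' free-swimming frame of [recoil_frame()], whose principal axis then serves
#' as the swimming axis; with \code{recoil = FALSE} the axis is the mean
#' head-to-tail direction of the raw data. Either way the result is
#' invariant to the fish's absolute position and heading.
#'
#' @param seq A \code{midline_seq} spanning at least 2 oscillation periods.
#' @param recoil Apply the free-swimming recoil correction first?
#' @return A \code{tail_kinematics} list: \code{h_mm}, \code{hdot_mm_s},
#'   \code{hprime}, \code{fps}, \code{body_length_mm}, \code{freq_hz}
#'   (dominant tail-beat frequency, NA when the tail is still).
#' @export
tail_kinematics <- function(seq, recoil = TRUE) {
  stopifnot(inherits(seq, "midline_seq"))
  seq <- midline_seq_to_mm(seq)
  nt <- length(seq$midlines)
  if (nt < 3) stop("insufficient-data: need at least 3 frames")
  if (recoil) seq <- recoil_frame(seq)
  head_pts <- t(vapply(seq$midlines, function(m) m[1, ], numeric(2)))
  tail_pts <- t(vapply(seq$midlines, function(m) m[nrow(m), ], numeric(2)))
  axis <- if (recoil) c(1, 0) else colMeans(tail_pts) - colMeans(head_pts)
  na <- sqrt(sum(axis^2))
  if (na == 0) axis <- c(1, 0) else axis <- axis / na
  nrm <- c(-axis[2], axis[1])
  centre <- colMeans(tail_pts)
  h <- as.numeric((tail_pts - matrix(centre, nt, 2, byrow = TRUE)) %*% nrm)
  hdot <- c(h[2] - h[1], (h[-(1:2)] - h[-((nt - 1):nt)]) / 2,
            h[nt] - h[nt - 1]) * seq$fps
  last_seg <- t(vapply(seq$midlines, function(m) {
    m[nrow(m), ] - m[nrow(m) - 1, ]
  }, numeric(2)))
  hprime <- as.numeric(last_seg %*% nrm) / as.numeric(last_seg %*% axis)
  bl <- arc_length(seq$midlines[[1]])
  freq <- dominant_frequency(h, seq$fps)
  structure(list(h_mm = h, hdot_mm_s = hdot, hprime = hprime, fps = seq$fps,
                 body_length_mm = bl, freq_hz = freq),
            class = "tail_kinematics")
}

dominant_frequency <- function(x, fs) {
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) return(NA_real_)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  pw[1] <- 0
  k <- which.max(pw[seq_len(floor(n / 2))])
  (k - 1) * fs / n
}

# Means over an integer number of oscillation periods (falls back to the
# full record for aperiodic input).
periodic_means <- function(tk) {
  n <- length(tk$h_mm)
  if (is.finite(tk$freq_hz) && tk$freq_hz > 0) {
    per <- tk$fps / tk$freq_hz
    n_use <- floor(floor((n - 1) / per) * per) + 1
    if (n_use >= per) n <- n_use
  }
  idx <- seq_len(n)
  list(hdot2 = mean(tk$hdot_mm_s[idx]^2), hprime2 = mean(tk$hprime[idx]^2))
}

#' Time-averaged elongated-body thrust at a candidate speed
#'
#' Lighthill's elongated-body mean thrust
#' \deqn{T(U) = \frac{m_a}{2}\left(\langle \dot h^2\rangle -
#'   U^2 \langle h'^2 \rangle\right)}
#' with added mass per unit length \eqn{m_a = \rho\pi(\mathrm{span}/2)^2},
#' averaged over an integer number of tail-beat periods. Units: Newtons.
#'
#' @param tk A \code{tail_kinematics} object.
#' @param U Candidate forward speed in body lengths per second (>= 0).
#' @param cfg A \code{propulsion_config}.
#' @return Mean thrust in N.
#' @export
mean_thrust <- function(tk, U, cfg = propulsion_config()) {
  stopifnot(inherits(tk, "tail_kinematics"), U >= 0)
  m_a <- cfg$water_density * pi * (cfg$tail_span_mm / 2000)^2   # kg/m
  mu <- periodic_means(tk)
  U_ms <- U * tk$body_length_mm / 1000
  hdot2 <- mu$hdot2 * 1e-6                                      # (m/s)^2
  (m_a / 2) * (hdot2 - U_ms^2 * mu$hprime2)
}

body_drag <- function(U_bl_s, tk, cfg) {
  U_ms <- U_bl_s * tk$body_length_mm / 1000
  0.5 * cfg$water_density * cfg$drag_coeff * cfg$wetted_area_mm2 * 1e-6 * U_ms^2
}

#' Steady swimming speed from the thrust-drag balance
#'
#' Solves \eqn{T(U) = D(U)} by bisection on the configured speed bracket,
#' with quadratic body drag
#' \eqn{D(U) = \frac{1}{2}\rho C_d A U^2}. With undulation present the
#' balance has a unique root because T decreases and D increases in U.
#'
#' @param tk A \code{tail_kinematics} object (or a \code{midline_seq}, which
#'   is converted first).
#' @param cfg A \code{propulsion_config}.
#' @param condition_label Text label carried into the result.
#' @return A \code{propulsion_result}: \code{steady_speed_bl_s},
#'   \code{mean_thrust_at_zero_speed} (N), \code{condition_label}.
#' @export
steady_speed <- function(tk, cfg = propulsion_config(),
                         condition_label = "") {
  if (inherits(tk, "midline_seq")) tk <- tail_kinematics(tk)
  stopifnot(inherits(tk, "tail_kinematics"))
  t0 <- mean_thrust(tk, 0, cfg)
  if (t0 < 0) stop("pre-condition violated: negative thrust at zero speed")
  drag_scale <- body_drag(1, tk, cfg)
  out <- structure(list(steady_speed_bl_s = 0,
                        mean_thrust_at_zero_speed = t0,
                        condition_label = condition_label),
                   class = "propulsion_result")
  if (t0 == 0) return(out)
  f <- function(U) mean_thrust(tk, U, cfg) - body_drag(U, tk, cfg)
  br <- cfg$speed_bracket_bl_s
  if (f(br[2]) > 0)
    stop("bracket error: thrust still exceeds drag at ", br[2],
         " BL/s; widen speed_bracket_bl_s")
  root <- stats::uniroot(f, interval = br, tol = 1e-12)$root
  if (abs(f(root)) > 1e-8 * max(drag_scale, 1e-12))
    root <- stats::uniroot(f, interval = c(max(0, root - 0.1), root + 0.1),
                           tol = .Machine$double.eps^0.75)$root
  out$steady_speed_bl_s <- root
  out
}

#' @export
print.propulsion_result <- function(x, ...) {
  cat(sprintf("Steady speed%s: %.3f BL/s (thrust at U=0: %.3e N)\n",
              if (nzchar(x$condition_label))
                paste0(" [", x$condition_label, "]") else "",
              x$steady_speed_bl_s, x$mean_thrust_at_zero_speed))
  invisible(x)
}

preset_speed <- function(params, cfg, duration_s = 2, fps = 100) {
  fld <- generate_bending_field(params, duration_s, fps)
  steady_speed(tail_kinematics(midlines_from_bending(fld, params)), cfg)
}

#' Compare swimming-speed distributions across kinematic conditions
#'
#' For each preset, draws \code{n_noise_reps} parameter sets by
#' multiplicative Gaussian jitter (factor \code{1 + N(0, cv^2)}, truncated at
#' 0.05) on the amplitudes and frequency, and computes the steady speed of
#' each draw. The tidy result mirrors a per-condition box plot.
#'
#' @param presets Named list of \code{wave_params} (default the three
#'   shipped presets).
#' @param cfg A \code{propulsion_config}.
#' @param n_noise_reps Replicates per condition.
#' @param jitter_cv Coefficient of variation of the jitter (0 disables it).
#' @param seed Integer seed.
#' @param duration_s,fps Kinematic record simulated per replicate.
#' @return data.frame with columns \code{condition}, \code{rep},
#'   \code{speed_bl_s}, \code{error} (NA or the bracket-error message).
#' @export
compare_conditions <- function(presets = wave_presets("all"),
                               cfg = propulsion_config(),
                               n_noise_reps = 20, jitter_cv = 0.1,
                               seed = 1, duration_s = 2, fps = 100) {
  stopifnot(length(presets) >= 2, !is.null(names(presets)))
  set.seed(seed)
  rows <- list()
  for (cond in names(presets)) {
    p0 <- presets[[cond]]
    for (r in seq_len(n_noise_reps)) {
      p <- p0
      if (jitter_cv > 0) {
        jit <- function(v) v * max(0.05, 1 + stats::rnorm(1, 0, jitter_cv))
        p$standing_amp_rad <- jit(p$standing_amp_rad)
        p$travelling_amp_rad <- jit(p$travelling_amp_rad)
        p$freq_hz <- jit(p$freq_hz)
      }
      sp <- tryCatch(preset_speed(p, cfg, duration_s, fps)$steady_speed_bl_s,
                     error = function(e) conditionMessage(e))
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, rep = r,
        speed_bl_s = if (is.numeric(sp)) sp else NA_real_,
        error = if (is.numeric(sp)) NA_character_ else sp)
    }
  }
  do.call(rbind, rows)
}

#' Search for a compensating pectoral standing wave
#'
#' Holding the caudal stiffness fixed, grid-searches standing-wave amplitude
#' and peak position for combinations that restore the fully flexible
#' preset's steady speed. Among grid points whose speed is within
#' \code{tol_frac} of the flexible speed, the least-effort one is selected:
#' the pair with the smallest standing amplitude (if no point is within
#' tolerance, the closest speed wins). Because recoil discounts rostral
#' bending (see [recoil_frame()]), the least-effort compensation places the
#' standing-wave peak caudal to the wildtype position.
#'
#' @param stiffness_gamma Fixed travelling-wave attenuation factor.
#' @param amp_grid Standing amplitudes searched (rad).
#' @param peak_grid Standing peak positions searched (BL fraction).
#' @param tol_frac Relative speed tolerance defining "compensated".
#' @param cfg A \code{propulsion_config}.
#' @param duration_s,fps Kinematic record per grid point.
#' @return List: \code{grid} (data.frame amp, peak, speed_bl_s,
#'   compensates), \code{best} (least-effort compensating row),
#'   \code{flexible_speed_bl_s}, \code{wildtype_peak_pos}.
#' @export
compensation_search <- function(stiffness_gamma = 0.3,
                                amp_grid = seq(0.04, 0.12, by = 0.01),
                                peak_grid = seq(0.25, 0.45, by = 0.05),
                                tol_frac = 0.05,
                                cfg = propulsion_config(),
                                duration_s = 2, fps = 100) {
  flex <- wave_presets("flexible")
  u_flex <- preset_speed(flex, cfg, duration_s, fps)$steady_speed_bl_s
  grid <- expand.grid(amp = amp_grid, peak = peak_grid)
  grid$speed_bl_s <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- flex
    p$stiffness_gamma <- stiffness_gamma
    p$standing_amp_rad <- grid$amp[i]
    p$standing_peak_pos <- grid$peak[i]
    grid$speed_bl_s[i] <- tryCatch(
      preset_speed(p, cfg, duration_s, fps)$steady_speed_bl_s,
      error = function(e) NA_real_)
  }
  grid$compensates <- !is.na(grid$speed_bl_s) &
    abs(grid$speed_bl_s - u_flex) <= tol_frac * u_flex
  best <- if (any(grid$compensates)) {
    hits <- grid[grid$compensates, ]
    hits[order(hits$amp, -hits$peak), ][1, ]
  } else {
    ok <- which(!is.na(grid$speed_bl_s))
    grid[ok[which.min(abs(grid$speed_bl_s[ok] - u_flex))], ]
  }
  list(grid = grid, best = best, flexible_speed_bl_s = u_flex,
       wildtype_peak_pos = flex$standing_peak_pos)
}
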