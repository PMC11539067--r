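#' Parameters of the standing + travelling wave kinematic model
#'
#' Zebrafish undulation is modelled as the superposition of a pectoral
#' standing wave (a Gaussian bending envelope that oscillates in place) and a
#' caudal travelling wave (a rostro-caudally propagating bending wave whose
#' amplitude grows towards the tail). Caudal stiffening is expressed by a
#' factor \code{stiffness_gamma} that scales the travelling wave caudal to
#' \code{stiffness_onset}. All amplitudes are local bending angles in radians
#' per segment; all positions are arc-length fractions of body length
#' (0 = snout, 1 = tail tip).
#'
#' @param body_length_mm Body length in mm (> 0).
#' @param n_segments Number of body segments (>= 10); midlines carry
#'   \code{n_segments + 1} points.
#' @param freq_hz Tail-beat frequency in Hz (> 0).
#' @param wavelength_bl Travelling wavelength in body lengths (> 0).
#' @param standing_amp_rad Peak standing bending amplitude (rad, >= 0).
#' @param standing_peak_pos Position of the standing-wave peak as a fraction
#'   of body length in [0, 1].
#' @param standing_width Gaussian envelope width (body-length fraction, > 0).
#' @param travelling_amp_rad Base travelling amplitude (rad, >= 0).
#' @param caudal_growth_exp Exponent (>= 0) of the power-law caudal growth of
#'   the travelling amplitude.
#' @param stiffness_gamma Factor in [0, 1] scaling the travelling wave caudal
#'   to \code{stiffness_onset}; 1 means fully flexible.
#' @param stiffness_onset Body-length fraction in [0, 1] where stiffening
#'   starts.
#' @return An object of class \code{wave_params} (a validated list).
#' @examples
#' p <- wave_params()
#' p$stiffness_gamma
#' @export
wave_params <- function(body_length_mm = 30,
                        n_segments = 50,
                        freq_hz = 2.5,
                        wavelength_bl = 1.0,
                        standing_amp_rad = 0.04,
                        standing_peak_pos = 0.25,
                        standing_width = 0.08,
                        travelling_amp_rad = 0.05,
                        caudal_growth_exp = 2,
                        stiffness_gamma = 1,
                        stiffness_onset = 0.5) {
  p <- list(body_length_mm = body_length_mm, n_segments = n_segments,
            freq_hz = freq_hz, wavelength_bl = wavelength_bl,
            standing_amp_rad = standing_amp_rad,
            standing_peak_pos = standing_peak_pos,
            standing_width = standing_width,
            travelling_amp_rad = travelling_amp_rad,
            caudal_growth_exp = caudal_growth_exp,
            stiffness_gamma = stiffness_gamma,
            stiffness_onset = stiffness_onset)
  validate_wave_params(p)
  structure(p, class = "wave_params")
}

validate_wave_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("invalid-parameter: non-finite or non-scalar wave parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  stopifnot(p$body_length_mm > 0, p$n_segments >= 10,
            p$n_segments == round(p$n_segments),
            p$freq_hz > 0, p$wavelength_bl > 0,
            p$standing_amp_rad >= 0,
            p$standing_peak_pos >= 0, p$standing_peak_pos <= 1,
            p$standing_width > 0,
            p$travelling_amp_rad >= 0, p$caudal_growth_exp >= 0,
            p$stiffness_gamma >= 0, p$stiffness_gamma <= 1,
            p$stiffness_onset >= 0, p$stiffness_onset <= 1)
  invisible(p)
}

#' @export
print.wave_params <- function(x, ...) {
  cat("Standing + travelling wave parameters\n")
  cat(sprintf("  body %.1f mm, %d segments, f = %.2f Hz, lambda = %.2f BL\n",
              x$body_length_mm, x$n_segments, x$freq_hz, x$wavelength_bl))
  cat(sprintf("  standing: amp %.3f rad, peak %.2f BL, width %.2f BL\n",
              x$standing_amp_rad, x$standing_peak_pos, x$standing_width))
  cat(sprintf("  travelling: amp %.3f rad, growth s^%.1f\n",
              x$travelling_amp_rad, x$caudal_growth_exp))
  cat(sprintf("  stiffness: gamma %.2f caudal to %.2f BL\n",
              x$stiffness_gamma, x$stiffness_onset))
  invisible(x)
}

#' Shipped wave-model presets
#'
#' Three parameter sets realizing the fully flexible (wildtype), caudally
#' stiffened, and compensated conditions. The stiff preset reduces the
#' travelling wave caudal to mid-body (gamma = 0.3); the compensated preset
#' keeps that stiffness but enlarges the pectoral standing wave (amplitude
#' x1.8) and shifts its peak caudally (0.25 -> 0.35 BL).
#'
#' @param condition One of \code{"flexible"}, \code{"stiff"},
#'   \code{"compensated"} (\code{"wildtype"} is an alias of
#'   \code{"flexible"}), or \code{"all"} for a named list of the three.
#' @return A \code{wave_params} object, or a named list of them.
#' @export
wave_presets <- function(condition = c("all", "flexible", "wildtype",
                                       "stiff", "compensated")) {
  condition <- match.arg(condition)
  base <- wave_params()
  presets <- list(
    flexible    = base,
    stiff       = wave_params(stiffness_gamma = 0.3, stiffness_onset = 0.5),
    compensated = wave_params(stiffness_gamma = 0.3, stiffness_onset = 0.5,
                              standing_amp_rad = base$standing_amp_rad * 1.8,
                              standing_peak_pos = 0.35)
  )
  if (condition == "all") return(presets)
  if (condition == "wildtype") condition <- "flexible"
  presets[[condition]]
}

# Stiffness factor gamma(s): 1 rostral to the onset, stiffness_gamma caudal,
# joined by a half-cosine ramp of width 0.05 BL so midline curvature stays
# continuous.
stiffness_profile <- function(s, gamma, onset, ramp = 0.05) {
  lo <- onset - ramp / 2
  g <- ifelse(s <= lo, 1,
              ifelse(s >= lo + ramp, gamma,
                     gamma + (1 - gamma) * (1 + cos(pi * (s - lo) / ramp)) / 2))
  g
}

#' Generate a bending field from wave parameters
#'
#' Evaluates the model bending angle
#' \deqn{\theta(s,t) = A_s G(s)\cos(2\pi f t) +
#'   \gamma(s) A_t s^{q} \cos(2\pi f t - 2\pi s/\lambda)}
#' on a regular time/segment grid. \code{G} is a Gaussian envelope with
#' maximum 1 at \code{standing_peak_pos}; \code{gamma(s)} drops from 1 to
#' \code{stiffness_gamma} across a half-cosine ramp at
#' \code{stiffness_onset}. Deterministic.
#'
#' @param params A \code{wave_params} object.
#' @param duration_s Record duration in seconds (> 0).
#' @param fps Sampling rate in frames per second (> 0).
#' @return A \code{bending_field}: list with \code{theta} (matrix
#'   [time, segment], radians), \code{times_s}, \code{s_frac}.
#' @export
generate_bending_field <- function(params, duration_s, fps) {
  validate_wave_params(params)
  stopifnot(duration_s > 0, fps > 0)
  if (fps < 2 * params$freq_hz)
    warning("fps below Nyquist for freq_hz: temporal aliasing likely")
  times <- seq(0, duration_s, by = 1 / fps)
  times <- times[times < duration_s + 1e-12]
  s <- seq(0, 1, length.out = params$n_segments)
  G <- exp(-(s - params$standing_peak_pos)^2 / (2 * params$standing_width^2))
  gam <- stiffness_profile(s, params$stiffness_gamma, params$stiffness_onset)
  trav_env <- gam * params$travelling_amp_rad * s^params$caudal_growth_exp
  stand_env <- params$standing_amp_rad * G
  ph <- 2 * pi * outer(params$freq_hz * times, rep(1, length(s)))
  lag <- 2 * pi * s / params$wavelength_bl
  theta <- sweep(cos(ph), 2, stand_env, "*") +
    sweep(cos(sweep(ph, 2, lag, "-")), 2, trav_env, "*")
  bending_field(theta, times, s)
}

#' Construct and validate a bending field
#'
#' @param theta Matrix of local bending angles (rad), rows = time,
#'   columns = segments.
#' @param times_s Sample times (s), strictly increasing.
#' @param s_frac Segment arc-length fractions, strictly increasing from 0 to 1.
#' @return A \code{bending_field} object.
#' @export
bending_field <- function(theta, times_s, s_frac) {
  theta <- as.matrix(theta)
  stopifnot(all(is.finite(theta)), nrow(theta) == length(times_s),
            ncol(theta) == length(s_frac), all(diff(s_frac) > 0),
            abs(s_frac[1]) < 1e-9, abs(s_frac[length(s_frac)] - 1) < 1e-9)
  structure(list(theta = theta, times_s = as.numeric(times_s),
                 s_frac = as.numeric(s_frac)),
            class = "bending_field")
}

#' @export
print.bending_field <- function(x, ...) {
  cat(sprintf("Bending field: %d frames x %d segments, %.2f s\n",
              nrow(x$theta), ncol(x$theta), diff(range(x$times_s))))
  invisible(x)
}

#' Reconstruct midlines from a bending field
#'
#' Integrates the inextensible body curve per frame: per-segment headings are
#' the cumulative sum of bending angles, points follow by summing unit
#' tangents scaled by \code{body_length_mm / n_segments}. The head sits at
#' the origin with the body extending along +x when straight, so arc length
#' equals \code{body_length_mm} by construction.
#'
#' @param field A \code{bending_field}.
#' @param params The \code{wave_params} the field was generated with (supplies
#'   body length and segment count).
#' @return A \code{midline_seq} (see [midline_seq()]) in mm units.
#' @export
midlines_from_bending <- function(field, params) {
  stopifnot(inherits(field, "bending_field"))
  if (ncol(field$theta) != params$n_segments)
    stop("field has ", ncol(field$theta), " segments but params expect ",
         params$n_segments)
  ds <- params$body_length_mm / params$n_segments
  nt <- nrow(field$theta)
  pts <- vector("list", nt)
  for (i in seq_len(nt)) {
    phi <- cumsum(field$theta[i, ])
    x <- c(0, cumsum(ds * cos(phi)))
    y <- c(0, cumsum(ds * sin(phi)))
    pts[[i]] <- cbind(x = x, y = y)
  }
  fps <- if (nt > 1) 1 / mean(diff(field$times_s)) else 1
  midline_seq(pts, fps = fps, units = "mm")
}

#' Bending angles of a midline sequence
#'
#' Inverse of [midlines_from_bending()]: per frame, segment headings from
#' consecutive point differences; bending angles are the wrapped differences
#' of consecutive headings, with the first segment's heading taken relative
#' to the frame's leading direction so a straight body maps to zero bending.
#'
#' @param seq A \code{midline_seq}.
#' @return A \code{bending_field} with \code{n_points - 1} segments.
#' @export
bending_series <- function(seq) {
  stopifnot(inherits(seq, "midline_seq"))
  nt <- length(seq$midlines)
  np <- nrow(seq$midlines[[1]])
  theta <- matrix(NA_real_, nt, np - 1)
  for (i in seq_len(nt)) {
    d <- diff(seq$midlines[[i]])
    phi <- atan2(d[, 2], d[, 1])
    th <- c(phi[1], diff(phi))
    # wrap into (-pi, pi]
    th[-1] <- atan2(sin(th[-1]), cos(th[-1]))
    theta[i, ] <- th
  }
  # first column is the absolute heading of segment 1; bending proper starts
  # at the second segment. Keep the convention of generate_bending_field by
  # treating segment 1's heading as bending relative to +x of the body frame.
  times <- (seq_len(nt) - 1) / seq$fps
  bending_field(theta, times, seq(0, 1, length.out = np - 1))
}

#' Fit a single dominant frequency to a bending field
#'
#' Finds the dominant temporal frequency (argmax of the mean power spectrum of
#' mean-subtracted bending over mid-body segments) and least-squares fits, per
#' segment, \eqn{\theta(s,t) \approx C(s)\cos(2\pi f t) + S(s)\sin(2\pi f t)}.
#' The complex amplitude profile \eqn{Z(s) = C(s) - i S(s)} carries the
#' spatial amplitude and phase of the oscillation.
#'
#' @param field A \code{bending_field} covering at least 2 oscillation
#'   periods of its dominant frequency.
#' @param mid_band Arc-length window used for the spectrum (default
#'   \code{c(0.3, 0.7)}).
#' @return A \code{wave_fit}: list with \code{freq_hz}, complex \code{Z},
#'   \code{amplitude} (= |Z|), \code{phase} (= arg Z), \code{s_frac},
#'   \code{low_power} flag.
#' @export
fit_single_frequency <- function(field, mid_band = c(0.3, 0.7)) {
  stopifnot(inherits(field, "bending_field"))
  t <- field$times_s
  nt <- length(t)
  fs <- 1 / mean(diff(t))
  th <- sweep(field$theta, 2, colMeans(field$theta))
  mid <- field$s_frac >= mid_band[1] & field$s_frac <= mid_band[2]
  if (!any(mid)) mid <- rep(TRUE, length(field$s_frac))
  spec <- Mod(stats::mvfft(th[, mid, drop = FALSE]))^2
  pw <- rowMeans(spec)[seq_len(floor(nt / 2))]
  pw[1] <- 0  # DC removed by mean subtraction; guard residual
  freqs <- (seq_len(nt) - 1) * fs / nt
  f <- freqs[which.max(pw)]
  if (f <= 0 || diff(range(t)) < 2 / f)
    stop("insufficient-data: record shorter than 2 periods of the dominant frequency")
  X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  B <- qr.solve(X, th)                    # 2 x n_segments
  Z <- complex(real = B[1, ], imaginary = -B[2, ])
  tone_pw <- mean(Mod(Z[mid])^2) / 2
  resid_pw <- mean((th[, mid, drop = FALSE] -
                      X %*% B[, mid, drop = FALSE])^2)
  low_power <- tone_pw < resid_pw
  if (low_power)
    warning("low-power: fitted tone below residual noise floor")
  structure(list(freq_hz = f, Z = Z, amplitude = Mod(Z), phase = Arg(Z),
                 s_frac = field$s_frac, low_power = low_power),
            class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  cat(sprintf("Single-frequency wave fit: f = %.3f Hz over %d segments\n",
              x$freq_hz, length(x$Z)))
  cat(sprintf("  peak |Z| = %.4f rad at s = %.2f BL%s\n",
              max(x$amplitude), x$s_frac[which.max(x$amplitude)],
              if (x$low_power) "  [low power]" else ""))
  invisible(x)
}

#' @export
coef.wave_fit <- function(object, ...) {
  data.frame(s_frac = object$s_frac, amplitude = object$amplitude,
             phase = object$phase)
}

#' @export
plot.wave_fit <- function(x, ...) {
  graphics::plot(x$s_frac, x$amplitude, type = "l",
                 xlab = "arc-length fraction", ylab = "|Z| (rad)",
                 main = sprintf("Bending amplitude envelope (f = %.2f Hz)",
                                x$freq_hz), ...)
  invisible(x)
}

#' Decompose a complex amplitude profile into standing and travelling waves
#'
#' Splits \code{Z(s)} into counter-propagating components via the spatial
#' analytic signal: the discrete Fourier transform of Z along s is separated
#' into positive- and negative-wavenumber halves (DC and Nyquist split
#' equally), giving \eqn{Z = Z_+ + Z_-}. The standing amplitude is
#' \code{2*pmin(|Z+|, |Z-|)} (the part that beats in place), the travelling
#' amplitude \code{||Z+| - |Z-||}, and the travelling index
#' travelling/(travelling + standing), with 0/0 defined as 0.
#'
#' @param Z Complex vector on >= 10 segments, or a \code{wave_fit}.
#' @return List with \code{standing}, \code{travelling} (amplitude
#'   envelopes), \code{travelling_index} per segment.
#' @export
decompose_standing_travelling <- function(Z) {
  if (inherits(Z, "wave_fit")) Z <- Z$Z
  n <- length(Z)
  stopifnot(is.complex(Z) || is.numeric(Z), n >= 10)
  Z <- as.complex(Z)
  F <- stats::fft(Z)
  w <- numeric(n)                       # weight of the positive-k half
  half <- ceiling(n / 2)
  w[1] <- 0.5                           # DC
  if (n %% 2 == 0) {
    w[2:half] <- 1
    w[half + 1] <- 0.5                  # Nyquist
  } else {
    w[2:half] <- 1
  }
  Zp <- stats::fft(F * w, inverse = TRUE) / n
  Zm <- Z - Zp
  ap <- Mod(Zp); am <- Mod(Zm)
  standing <- 2 * pmin(ap, am)
  travelling <- abs(ap - am)
  tot <- standing + travelling
  idx <- ifelse(tot > 0, travelling / tot, 0)
  list(standing = standing, travelling = travelling, travelling_index = idx)
}

#' Pectoral bending peak position
#'
#' Arc-length fraction of the maximum of a bending amplitude envelope,
#' restricted to a rostral window (default the front half of the body). Ties
#' break to the most rostral maximum; the position is refined below segment
#' resolution by parabolic interpolation around the argmax.
#'
#' @param envelope Non-negative amplitude envelope (e.g. \code{|Z|} from
#'   [fit_single_frequency()]), or a \code{wave_fit}.
#' @param s_frac Arc-length fractions matching \code{envelope} (taken from
#'   the fit when a \code{wave_fit} is given).
#' @param rostral_window Interval of body-length fractions searched.
#' @return Peak position in [0, 1] (body-length fraction).
#' @export
pectoral_peak_position <- function(envelope, s_frac = NULL,
                                   rostral_window = c(0, 0.5)) {
  if (inherits(envelope, "wave_fit")) {
    s_frac <- envelope$s_frac
    envelope <- envelope$amplitude
  }
  if (is.null(s_frac)) s_frac <- seq(0, 1, length.out = length(envelope))
  stopifnot(all(envelope >= 0), length(envelope) == length(s_frac))
  in_win <- s_frac >= rostral_window[1] & s_frac <= rostral_window[2]
  env <- envelope[in_win]
  s <- s_frac[in_win]
  if (length(env) == 0 || all(env == 0))
    stop("undefined-peak: amplitude envelope is zero over the rostral window")
  k <- which(env == max(env))[1]        # rostral tie-break
  p <- s[k]
  if (k > 1 && k < length(env)) {       # parabolic refinement
    y1 <- env[k - 1]; y2 <- env[k]; y3 <- env[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      p <- s[k] + delta * (s[k + 1] - s[k])
    }
  }
  min(max(p, rostral_window[1]), rostral_window[2])
}
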