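#' Construct a field-potential trace
#'
#' @param samples Voltage samples.
#' @param fs Sampling rate in Hz; must exceed twice the 500 Hz passband top.
#' @param stim_time_s Stimulus time (s) used as the t = 0 reference.
#' @return An \code{ephys_trace} object.
#' @export
ephys_trace <- function(samples, fs, stim_time_s = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 2 * 500)
  structure(list(samples = as.numeric(samples), fs = fs,
                 stim_time_s = stim_time_s),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("Field potential: %.2f s at %g Hz, stimulus at %.3f s\n",
              length(x$samples) / x$fs, x$fs, x$stim_time_s))
  invisible(x)
}

#' Band-pass filter a field potential (300-500 Hz)
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, matching
#' the hardware pass window used for tank recordings of Mauthner-cell field
#' potentials. Passband gain at 400 Hz stays above 0.85; 50 Hz hum and
#' kilohertz noise are attenuated below 0.1.
#'
#' @param trace An \code{ephys_trace}.
#' @param low,high Band edges in Hz.
#' @return The filtered \code{ephys_trace}.
#' @export
bandpass <- function(trace, low = 300, high = 500) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$fs <= 2 * high)
    stop("sampling rate too low for a ", high, " Hz passband")
  bf <- signal::butter(4, c(low, high) / (trace$fs / 2), type = "pass")
  trace$samples <- filtfilt_padded(bf, trace$samples, trace$fs, pad_s = 0.2)
  trace
}

# Zero-phase filtering with reflection padding so start/end transients do
# not leak into the trace.
filtfilt_padded <- function(bf, x, fs, pad_s = 0.05) {
  n <- length(x)
  np <- min(n - 1, max(64, round(pad_s * fs)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(np + n)]
}

#' Notch out 50 Hz mains hum
#'
#' Zero-phase second-order Butterworth band-stop centred on 50 Hz — a
#' software Hum Bug. Narrow enough (default +/- 2.5 Hz) to leave broadband
#' spike waveforms essentially untouched.
#'
#' @param trace An \code{ephys_trace}.
#' @param centre Hum frequency (Hz).
#' @param q Quality factor; the stop band spans \code{centre/q} Hz.
#' @return The filtered \code{ephys_trace}.
#' @export
notch50 <- function(trace, centre = 50, q = 10) {
  stopifnot(inherits(trace, "ephys_trace"))
  half_bw <- centre / q / 2
  bf <- signal::butter(2, c(centre - half_bw, centre + half_bw) /
                         (trace$fs / 2), type = "stop")
  trace$samples <- filtfilt_padded(bf, trace$samples, trace$fs,
                                   pad_s = 0.2)
  trace
}

#' Detect spikes by a robust amplitude threshold
#'
#' Threshold at \code{k_mad} times the median absolute deviation (scaled to
#' estimate the noise sd) of the filtered trace. A band-pass-filtered spike
#' rings at the passband centre frequency, so candidate events are local
#' maxima of the signal envelope (modulus of the analytic signal), which
#' rises once per spike rather than once per ring cycle. Detections closer
#' than the refractory interval are thinned (larger event wins); each
#' event's time and amplitude come from the largest absolute sample within
#' the envelope peak.
#'
#' @param trace A filtered \code{ephys_trace}.
#' @param k_mad Threshold multiplier (default 5).
#' @param refractory_s Minimum spacing between detections (default 2 ms).
#' @return A \code{spike_train}: \code{times_s}, \code{amplitudes}
#'   (peak absolute values), \code{class} (unclassified \code{NA}),
#'   \code{stim_time_s}, \code{threshold}.
#' @export
detect_spikes <- function(trace, k_mad = 5, refractory_s = 0.002) {
  stopifnot(inherits(trace, "ephys_trace"))
  x <- trace$samples
  if (length(x) < 3) stop("empty or degenerate trace")
  thr <- k_mad * stats::mad(x)
  env <- Mod(analytic_signal(x))
  n <- length(env)
  is_peak <- env > thr &
    env >= c(-Inf, env[-n]) & env > c(env[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) > 1) {        # refractory thinning, larger event wins
    ord <- cand[order(-env[cand])]
    taken <- numeric(0)
    min_gap <- refractory_s * trace$fs
    for (i in ord) {
      if (all(abs(i - taken) >= min_gap)) taken <- c(taken, i)
    }
    cand <- sort(taken)
  }
  # event time = envelope peak (symmetric around the spike centre);
  # amplitude = strongest absolute sample within the event
  half <- max(1, round(refractory_s * trace$fs / 2))
  a <- abs(x)
  amps <- vapply(cand, function(i) {
    max(a[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  spike_train(times_s = (cand - 1) / trace$fs, amplitudes = amps,
              class = rep(NA_character_, length(cand)),
              stim_time_s = trace$stim_time_s, threshold = thr)
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  F <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(F * h, inverse = TRUE) / n
}

#' Construct a spike train
#'
#' @param times_s Strictly increasing spike times (s).
#' @param amplitudes Peak amplitudes.
#' @param class Per-spike class ("small"/"large" or NA).
#' @param stim_time_s Stimulus reference time.
#' @param threshold Detection threshold, if any.
#' @return A \code{spike_train} object.
#' @export
spike_train <- function(times_s, amplitudes = rep(NA_real_, length(times_s)),
                        class = rep(NA_character_, length(times_s)),
                        stim_time_s = 0, threshold = NA_real_) {
  stopifnot(all(diff(times_s) > 0) || length(times_s) <= 1,
            length(amplitudes) == length(times_s),
            length(class) == length(times_s))
  structure(list(times_s = as.numeric(times_s),
                 amplitudes = as.numeric(amplitudes),
                 class = as.character(class),
                 stim_time_s = stim_time_s, threshold = threshold),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cl <- table(factor(x$class, levels = c("small", "large")))
  cat(sprintf("Spike train: %d spikes (%d small, %d large)\n",
              length(x$times_s), cl["small"], cl["large"]))
  invisible(x)
}

#' Split spikes into small and large amplitude classes
#'
#' One-dimensional two-means clustering of log-amplitudes with deterministic
#' quantile initialization (25th and 75th percentiles). When the two class
#' centres end up closer than \code{min_sep} log-units the amplitudes are
#' treated as unimodal: every spike is labelled with one class and the
#' result is flagged.
#'
#' @param train A \code{spike_train} with >= 2 spikes.
#' @param min_sep Minimum centre separation (log units) for a two-class
#'   split.
#' @return The train with \code{class} filled in, plus fields
#'   \code{boundary} (amplitude separating the classes) and
#'   \code{unimodal} flag.
#' @export
classify_amplitude <- function(train, min_sep = 0.2) {
  stopifnot(inherits(train, "spike_train"), length(train$times_s) >= 2)
  la <- log(train$amplitudes)
  c1 <- stats::quantile(la, 0.25, names = FALSE)
  c2 <- stats::quantile(la, 0.75, names = FALSE)
  for (it in 1:100) {
    assign_large <- abs(la - c2) < abs(la - c1)
    if (all(assign_large) || !any(assign_large)) break
    n1 <- mean(la[!assign_large]); n2 <- mean(la[assign_large])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  if (!any(assign_large) || all(assign_large) || (c2 - c1) < min_sep) {
    train$class <- rep("large", length(la))
    train$unimodal <- TRUE
    train$boundary <- NA_real_
    return(train)
  }
  train$class <- ifelse(assign_large, "large", "small")
  train$boundary <- exp((c1 + c2) / 2)
  train$unimodal <- FALSE
  train
}

#' Instantaneous spike frequency
#'
#' ISF at spike i is the reciprocal inter-spike interval
#' \eqn{1/(t_i - t_{i-1})}, assigned at spike i, with times reported
#' relative to the stimulus.
#'
#' @param train A \code{spike_train}.
#' @return data.frame \code{time_s} (stimulus-aligned), \code{isf_hz};
#'   empty (with a message) for fewer than 2 spikes.
#' @export
instantaneous_frequency <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times_s) < 2) {
    message("fewer than 2 spikes: empty ISF series")
    return(data.frame(time_s = numeric(0), isf_hz = numeric(0)))
  }
  data.frame(time_s = train$times_s[-1] - train$stim_time_s,
             isf_hz = 1 / diff(train$times_s))
}

#' Peristimulus time histogram across individuals
#'
#' Per train, counts spikes in bins of a window around the stimulus
#' (t = 0); the result is the mean count per bin across trains.
#'
#' @param trains List of \code{spike_train}, all stimulus-aligned.
#' @param window Window around t = 0 in seconds, \code{c(lo, hi)}.
#' @param bin_width Bin width (s).
#' @param class_filter Optional class ("large"/"small") to restrict counts.
#' @return List: \code{breaks}, \code{mid}, \code{mean_counts},
#'   \code{counts} (matrix train x bin), \code{t0_bin} (index of the bin
#'   containing t = 0).
#' @export
psth <- function(trains, window = c(-0.1, 0.3), bin_width = 0.01,
                 class_filter = NULL) {
  stopifnot(length(trains) >= 1, window[2] > window[1], bin_width > 0)
  # anchor bin edges at t = 0 so the stimulus bin is exact
  k_lo <- floor(round(-window[1] / bin_width, 9))
  k_hi <- ceiling(round(window[2] / bin_width, 9))
  breaks <- (-k_lo:k_hi) * bin_width
  if (length(breaks) < 2) stop("empty window")
  counts <- t(vapply(trains, function(tr) {
    t_rel <- tr$times_s - tr$stim_time_s
    if (!is.null(class_filter)) t_rel <- t_rel[tr$class %in% class_filter]
    t_rel <- t_rel[t_rel >= breaks[1] & t_rel < breaks[length(breaks)]]
    tabulate(findInterval(t_rel, breaks), nbins = length(breaks) - 1)
  }, numeric(length(breaks) - 1)))
  if (length(trains) == 1) counts <- matrix(counts, nrow = 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(breaks = breaks, mid = mids, mean_counts = colMeans(counts),
       counts = counts,
       t0_bin = findInterval(0, breaks))
}

#' Read / write ephys traces as CSV
#'
#' Two-column CSV (\code{time_s, voltage}); stimulus time in a JSON sidecar.
#'
#' @param trace An \code{ephys_trace}.
#' @param path CSV path.
#' @export
write_ephys_csv <- function(trace, path) {
  df <- data.frame(time_s = (seq_along(trace$samples) - 1) / trace$fs,
                   voltage = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = trace$fs, stim_time_s = trace$stim_time_s),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ephys_csv
#' @export
read_ephys_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  ephys_trace(df$voltage, fs = meta$fs, stim_time_s = meta$stim_time_s)
}
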