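#' Default rostro-caudally tapering body half-width profile
#'
#' Half-width of the fish silhouette as a fraction of body length: near-zero
#' at the snout, maximal (~6% BL) around a quarter of the body, tapering to a
#' point at the tail tip.
#'
#' @param s Arc-length fractions in [0, 1].
#' @return Half-widths in body-length fraction.
#' @export
body_width_profile <- function(s) {
  shape <- (s + 0.02)^0.35 * (1 - s)^1.1
  0.06 * shape / max((seq(0, 1, 0.005) + 0.02)^0.35 *
                       (1 - seq(0, 1, 0.005))^1.1)
}

#' Render a midline sequence into grayscale video frames
#'
#' Draws, per frame, a filled dark fish silhouette (the midline swept by a
#' tapering half-width profile) on a bright background, then adds zero-mean
#' Gaussian pixel noise and quantizes to 8-bit. Deterministic for a seed.
#' Emulates top-down high-speed recordings of a single swimming fish.
#'
#' @param seq A \code{midline_seq} in mm.
#' @param px_per_mm Pixel scale (> 0).
#' @param frame_dim Frame size \code{c(width, height)} in px; chosen to
#'   contain the fish with a margin when \code{NULL}.
#' @param width_profile Function mapping arc-length fraction to half-width in
#'   body-length fraction.
#' @param fish_value,bg_value Mean silhouette / background intensities
#'   (0-255).
#' @param bg_noise_sd Gaussian pixel noise sd (intensity units).
#' @param seed Integer seed.
#' @return A \code{frame_stack}: list with \code{frames} (list of integer
#'   matrices [y, x], 0-255), \code{masks} (ground-truth logical silhouettes),
#'   \code{px_per_mm}, \code{fps}, and \code{ground_truth} (the input
#'   midlines in px coordinates).
#' @export
render_frames <- function(seq, px_per_mm = 3, frame_dim = NULL,
                          width_profile = body_width_profile,
                          fish_value = 60, bg_value = 200,
                          bg_noise_sd = 8, seed = 1) {
  stopifnot(inherits(seq, "midline_seq"), px_per_mm > 0)
  seq <- midline_seq_to_mm(seq)
  np <- nrow(seq$midlines[[1]])
  bl <- arc_length(seq$midlines[[1]])
  s <- seq(0, 1, length.out = np)
  hw_mm <- width_profile(s) * bl
  all_pts <- do.call(rbind, seq$midlines)
  margin <- max(hw_mm) + 2 / px_per_mm
  x0 <- min(all_pts[, 1]) - margin; x1 <- max(all_pts[, 1]) + margin
  y0 <- min(all_pts[, 2]) - margin; y1 <- max(all_pts[, 2]) + margin
  if (is.null(frame_dim)) {
    frame_dim <- c(ceiling((x1 - x0) * px_per_mm) + 1,
                   ceiling((y1 - y0) * px_per_mm) + 1)
  } else if ((x1 - x0) * px_per_mm > frame_dim[1] ||
             (y1 - y0) * px_per_mm > frame_dim[2]) {
    bad <- which(vapply(seq$midlines, function(m) {
      any(m[, 1] < x0 | m[, 1] > x1 | m[, 2] < y0 | m[, 2] > y1)
    }, logical(1)))
    stop("out-of-frame: fish exceeds frame bounds in frames ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  W <- frame_dim[1]; H <- frame_dim[2]
  px_x <- (seq_len(W) - 0.5) / px_per_mm + x0
  px_y <- (seq_len(H) - 0.5) / px_per_mm + y0
  set.seed(seed)
  frames <- masks <- vector("list", length(seq$midlines))
  gt_px <- vector("list", length(seq$midlines))
  for (f in seq_along(seq$midlines)) {
    m <- seq$midlines[[f]]
    gt_px[[f]] <- cbind((m[, 1] - x0) * px_per_mm, (m[, 2] - y0) * px_per_mm)
    # bounding window of this frame's fish
    ix <- which(px_x >= min(m[, 1]) - margin & px_x <= max(m[, 1]) + margin)
    iy <- which(px_y >= min(m[, 2]) - margin & px_y <= max(m[, 2]) + margin)
    gx <- rep(px_x[ix], times = length(iy))
    gy <- rep(px_y[iy], each = length(ix))
    inside <- rep(FALSE, length(gx))
    for (k in seq_len(np - 1)) {       # distance to segment k vs local width
      ax <- m[k, 1]; ay <- m[k, 2]
      bx <- m[k + 1, 1]; by <- m[k + 1, 2]
      vx <- bx - ax; vy <- by - ay
      l2 <- vx * vx + vy * vy
      tt <- pmin(1, pmax(0, ((gx - ax) * vx + (gy - ay) * vy) / l2))
      dx <- gx - (ax + tt * vx); dy <- gy - (ay + tt * vy)
      wloc <- hw_mm[k] + tt * (hw_mm[k + 1] - hw_mm[k])
      inside <- inside | (dx * dx + dy * dy <= wloc * wloc)
    }
    img <- matrix(bg_value, H, W)
    sub <- matrix(inside, length(ix), length(iy))
    img[iy, ix] <- img[iy, ix] + t(sub) * (fish_value - bg_value)
    msk <- matrix(FALSE, H, W)
    msk[iy, ix] <- t(sub)
    if (bg_noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, bg_noise_sd), H, W)
    frames[[f]] <- matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)
    masks[[f]] <- msk
  }
  structure(list(frames = frames, masks = masks, px_per_mm = px_per_mm,
                 fps = seq$fps, origin_mm = c(x0, y0),
                 ground_truth = list(midlines_px = gt_px,
                                     midlines_mm = seq$midlines)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %dx%d px, %.1f fps, %.1f px/mm\n",
              length(x$frames), d[2], d[1], x$fps, x$px_per_mm))
  invisible(x)
}

#' Arena specification for counter-current trials
#'
#' @param width_mm,height_mm Arena dimensions (> 0); the stream runs along
#'   the long (x) axis and "lateral" means the y coordinate.
#' @param stream_speed_label One of \code{"slow"}, \code{"medium"},
#'   \code{"fast"} — categorical labels for the three pump flows
#'   (172, 240, 277 ml/s); flow magnitude is metadata only.
#' @param centre_band_frac Fraction of the arena width (y extent) treated as
#'   the centre band, in (0, 1].
#' @return An \code{arena_spec} list.
#' @export
arena_spec <- function(width_mm = 300, height_mm = 100,
                       stream_speed_label = c("medium", "slow", "fast"),
                       centre_band_frac = 1 / 3) {
  stream_speed_label <- match.arg(stream_speed_label)
  stopifnot(width_mm > 0, height_mm > 0,
            centre_band_frac > 0, centre_band_frac <= 1)
  flows <- c(slow = 172, medium = 240, fast = 277)    # ml/s, metadata
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 stream_speed_label = stream_speed_label,
                 flow_ml_s = unname(flows[stream_speed_label]),
                 centre_band_frac = centre_band_frac),
            class = "arena_spec")
}

#' Simulate an arena trajectory for a genotype preset
#'
#' Reflected biased random walk in arena coordinates. The wildtype preset is
#' pulled towards the arena's longitudinal centre line (mean-reverting
#' Ornstein-Uhlenbeck-style lateral dynamics) with small step dispersion;
#' the mutant preset has zero pull and larger dispersion, so it disperses
#' over the arena. Positions are reflected at the walls.
#'
#' @param spec An \code{arena_spec}.
#' @param preset \code{"wildtype"} or \code{"mutant"}.
#' @param duration_s,fps Record length and sampling rate
#'   (\code{duration_s * fps >= 100}).
#' @param pull Mean-reversion rate (1/s) towards the centre line for the
#'   wildtype preset.
#' @param step_sd_wt,step_sd_mut Lateral step dispersion (mm per sqrt(s)).
#' @param seed Integer seed.
#' @return A \code{trajectory} (see [trajectory()]) with attribute
#'   \code{ground_truth} (the preset label and parameters).
#' @export
simulate_arena_track <- function(spec = arena_spec(),
                                 preset = c("wildtype", "mutant"),
                                 duration_s = 30, fps = 10,
                                 pull = 1.5, step_sd_wt = 25,
                                 step_sd_mut = 60, seed = 1) {
  preset <- match.arg(preset)
  n <- round(duration_s * fps)
  stopifnot(n >= 100)
  set.seed(seed)
  dt <- 1 / fps
  kappa <- if (preset == "wildtype") pull else 0
  sd_step <- if (preset == "wildtype") step_sd_wt else step_sd_mut
  cy <- spec$height_mm / 2
  y <- numeric(n); x <- numeric(n)
  y[1] <- cy; x[1] <- spec$width_mm / 2
  for (i in 2:n) {
    y[i] <- y[i - 1] - kappa * (y[i - 1] - cy) * dt +
      stats::rnorm(1, 0, sd_step * sqrt(dt))
    x[i] <- x[i - 1] + stats::rnorm(1, 0, sd_step * sqrt(dt))
  }
  x <- reflect_into(x, 0, spec$width_mm)
  y <- reflect_into(y, 0, spec$height_mm)
  tr <- trajectory(times_s = (seq_len(n) - 1) * dt, x = x, y = y, fps = fps)
  attr(tr, "ground_truth") <- list(preset = preset, pull = kappa,
                                   step_sd = sd_step, seed = seed)
  tr
}

# Reflect coordinates into [lo, hi] (billiard reflection, handles multiple
# bounces).
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  u <- (v - lo) %% (2 * span)
  lo + ifelse(u > span, 2 * span - u, u)
}

#' Simulate a Mauthner-cell field-potential trace
#'
#' Places biphasic spike templates (~1 ms, derivative-of-Gaussian shape) of
#' two amplitude classes at given times, then adds 50 Hz mains hum and white
#' Gaussian noise. The stimulus time is the t = 0 reference carried in the
#' trace.
#'
#' @param large_times,small_times Spike times in seconds (relative to trace
#'   start) for the large and small amplitude classes.
#' @param duration_s Trace duration.
#' @param fs Sampling rate (default 25 kHz).
#' @param amp_large,amp_small Peak template amplitudes
#'   (\code{amp_large > amp_small > 0}).
#' @param hum_amp 50 Hz hum amplitude.
#' @param noise_sd White noise sd.
#' @param stim_time_s Stimulus time (s).
#' @param seed Integer seed.
#' @return An \code{ephys_trace} (see [ephys_trace()]) with attribute
#'   \code{ground_truth} (spike times and classes).
#' @export
simulate_field_potential <- function(large_times, small_times = numeric(0),
                                     duration_s = 2, fs = 25000,
                                     amp_large = 10, amp_small = 4,
                                     hum_amp = 1, noise_sd = 1,
                                     stim_time_s = 0, seed = 1) {
  stopifnot(amp_large > amp_small, amp_small > 0,
            all(large_times >= 0), all(large_times <= duration_s),
            all(small_times >= 0), all(small_times <= duration_s))
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  tmpl <- spike_template(fs)
  half <- (length(tmpl) - 1) / 2
  all_t <- c(large_times, small_times)
  all_a <- c(rep(amp_large, length(large_times)),
             rep(amp_small, length(small_times)))
  if (length(all_t) > 1) {
    gaps <- diff(sort(all_t))
    if (any(gaps < length(tmpl) / fs))
      warning("overlapping spikes closer than the template width; ",
              "superposition kept")
  }
  for (k in seq_along(all_t)) {
    c0 <- round(all_t[k] * fs) + 1
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + all_a[k] * tmpl[ok]
  }
  if (hum_amp > 0) x <- x + hum_amp * sin(2 * pi * 50 * t)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  tr <- ephys_trace(x, fs = fs, stim_time_s = stim_time_s)
  attr(tr, "ground_truth") <- list(
    times_s = all_t, class = rep(c("large", "small"),
                                 c(length(large_times), length(small_times))),
    amp = all_a, seed = seed)
  tr
}

# Biphasic ~1 ms template: derivative of a Gaussian (sigma 0.2 ms), peak
# normalized to 1.
spike_template <- function(fs, sigma_s = 2e-4, half_width_s = 6e-4) {
  half <- round(half_width_s * fs)
  tt <- (-half:half) / fs
  w <- -tt * exp(-tt^2 / (2 * sigma_s^2))
  w / max(abs(w))
}

#' Simulate an axon cross-section image
#'
#' Non-overlapping bright disks (axons) inside a region of interest on a dark
#' background, with mild Gaussian blur and pixel noise. Ground truth lists
#' centres and diameters.
#'
#' @param n_axons Number of axons (>= 0).
#' @param diameter_mean_px,diameter_sd_px Disk diameter distribution (px).
#' @param roi_polygon Two-column matrix of ROI vertices (px); default a
#'   triangle inside a 200x200 image, mirroring the triangular ROI used for
#'   spinal-cord sections.
#' @param img_dim Image size \code{c(width, height)}.
#' @param blur_sigma_px Gaussian blur sigma.
#' @param noise_sd Pixel noise sd (intensity in [0, 1] units).
#' @param max_tries Placement retries before a packing error.
#' @param seed Integer seed.
#' @return List with \code{image} (matrix [y, x] in [0, 1]),
#'   \code{roi_polygon}, and \code{ground_truth} (data.frame x, y,
#'   diameter_px).
#' @export
simulate_axon_image <- function(n_axons = 50, diameter_mean_px = 8,
                                diameter_sd_px = 1.5, roi_polygon = NULL,
                                img_dim = c(200, 200), blur_sigma_px = 0.8,
                                noise_sd = 0.02, max_tries = 5000, seed = 1) {
  stopifnot(n_axons >= 0, diameter_mean_px > 0)
  if (is.null(roi_polygon))
    roi_polygon <- cbind(x = c(20, 180, 100), y = c(30, 30, 185))
  set.seed(seed)
  W <- img_dim[1]; H <- img_dim[2]
  centres <- matrix(numeric(0), 0, 2)
  diams <- numeric(0)
  tries <- 0
  while (nrow(centres) < n_axons) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("packing error: could not place ", n_axons,
           " non-overlapping axons in the ROI after ", max_tries, " tries")
    d <- max(2, stats::rnorm(1, diameter_mean_px, diameter_sd_px))
    cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
    if (!point_in_polygon(cx, cy, roi_polygon)) next
    # margin so the full disk stays inside the ROI and clear of neighbours
    if (!all(point_in_polygon(cx + c(-1, 1, 0, 0) * (d / 2 + 1),
                              cy + c(0, 0, -1, 1) * (d / 2 + 1),
                              roi_polygon))) next
    if (nrow(centres) > 0) {
      dd <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
      if (any(dd < (diams + d) / 2 + 3)) next
    }
    centres <- rbind(centres, c(cx, cy))
    diams <- c(diams, d)
  }
  img <- matrix(0.08, H, W)
  if (n_axons > 0) {
    xg <- matrix(rep(seq_len(W), each = H), H, W)
    yg <- matrix(rep(seq_len(H), W), H, W)
    for (k in seq_len(n_axons)) {
      disk <- (xg - centres[k, 1])^2 + (yg - centres[k, 2])^2 <=
        (diams[k] / 2)^2
      img[disk] <- 0.9
    }
  }
  if (blur_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = blur_sigma_px))
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  img[] <- pmin(1, pmax(img, 0))
  list(image = img, roi_polygon = roi_polygon,
       ground_truth = data.frame(x = centres[, 1], y = centres[, 2],
                                 diameter_px = diams))
}

# Ray-casting point-in-polygon; vectorized over points.
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Simulate a C-start escape midline sequence
#'
#' A straight body that, after the stimulus, bends into a C within ~25 ms
#' and then unwinds — the stereotyped Mauthner-driven escape. Useful as a
#' ground-truth fixture for stimulus-aligned tortuosity analyses of
#' high-speed (936 fps) escape recordings.
#'
#' @param duration_s Record length (default 0.5 s).
#' @param fps Frame rate (default 936, the escape-camera rate).
#' @param stim_time_s Stimulus time.
#' @param latency_s Onset latency of the bend after the stimulus.
#' @param peak_curvature_total Total body turning at the C-bend apex (rad).
#' @param rise_s,decay_s Bend rise and unwind time constants.
#' @param body_length_mm,n_points Body geometry.
#' @return A \code{midline_seq} with attribute \code{ground_truth}
#'   (stim time, apex time).
#' @export
simulate_escape_sequence <- function(duration_s = 0.5, fps = 936,
                                     stim_time_s = 0.1, latency_s = 0.01,
                                     peak_curvature_total = 4.5,
                                     rise_s = 0.012, decay_s = 0.05,
                                     body_length_mm = 30, n_points = 51) {
  nt <- round(duration_s * fps)
  t <- (seq_len(nt) - 1) / fps
  onset <- stim_time_s + latency_s
  amp <- ifelse(t < onset, 0,
                peak_curvature_total *
                  (1 - exp(-(t - onset) / rise_s)) *
                  exp(-(t - onset) / decay_s))
  # normalize so the peak reaches peak_curvature_total
  if (max(amp) > 0) amp <- amp * peak_curvature_total / max(amp)
  ns <- n_points - 1
  pts <- vector("list", nt)
  ds <- body_length_mm / ns
  for (i in seq_len(nt)) {
    theta <- rep(amp[i] / ns, ns)       # uniform bend -> circular arc
    phi <- cumsum(theta)
    pts[[i]] <- cbind(c(0, cumsum(ds * cos(phi))),
                      c(0, cumsum(ds * sin(phi))))
  }
  out <- midline_seq(pts, fps = fps, units = "mm")
  attr(out, "ground_truth") <- list(stim_time_s = stim_time_s,
                                    apex_time_s = t[which.max(amp)],
                                    peak_curvature_total = peak_curvature_total)
  out
}
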