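# Shared fixtures, built in code at test time.

# A straight midline of n collinear points spanning length L (mm).
straight_midline <- function(n = 51, L = 30) {
  midline(cbind(seq(0, L, length.out = n), rep(0, n)))
}

# A circular-arc midline of total turning `total` rad and arc length L.
arc_midline <- function(total, n = 51, L = 30) {
  R <- L / total
  phi <- seq(0, total, length.out = n)
  midline(cbind(R * sin(phi), R * (1 - cos(phi))))
}

# Small bending field with known content: pure single tone per segment.
tone_field <- function(amp_profile, freq = 2.5, fps = 100, duration = 2,
                       phase = rep(0, length(amp_profile))) {
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  theta <- sapply(seq_along(amp_profile), function(j)
    amp_profile[j] * cos(2 * pi * freq * t - phase[j]))
  bending_field(theta, t, seq(0, 1, length.out = length(amp_profile)))
}

# Deterministic small rendered stack of a gently swimming fish.
small_stack <- function(duration = 1, fps = 50, seed = 7, px_per_mm = 5,
                        preset = wave_presets("flexible")) {
  fld <- generate_bending_field(preset, duration, fps)
  render_frames(midlines_from_bending(fld, preset), px_per_mm = px_per_mm,
                seed = seed)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
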