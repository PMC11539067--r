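test_that("zero amplitudes give an identically zero field and gamma = 1 is exact", {
  p0 <- wave_params(standing_amp_rad = 0, travelling_amp_rad = 0)
  f0 <- generate_bending_field(p0, 1, 50)
  expect_true(all(f0$theta == 0))

  p1 <- wave_params(stiffness_gamma = 1)
  p2 <- wave_params(stiffness_gamma = 1)
  expect_identical(generate_bending_field(p1, 1, 50)$theta,
                   generate_bending_field(p2, 1, 50)$theta)
})

test_that("invalid parameters error and sub-Nyquist sampling warns", {
  expect_error(wave_params(freq_hz = NA), "invalid-parameter")
  expect_error(wave_params(stiffness_gamma = 1.5))
  p <- wave_params(freq_hz = 2.5)
  expect_warning(generate_bending_field(p, 1, 4), "aliasing|Nyquist")
})

test_that("pure travelling wave has spatial phase slope 2*pi/wavelength", {
  # closed-form phase oracle: the generating cosine at segment s has phase
  # -2*pi*s/lambda, so the fitted per-segment phase must fall on that line
  p <- wave_params(standing_amp_rad = 0, travelling_amp_rad = 0.05,
                   wavelength_bl = 0.8, caudal_growth_exp = 0)
  fld <- generate_bending_field(p, 2, 100)
  fit <- fit_single_frequency(fld)
  ph <- fit$phase
  s <- fit$s_frac
  # unwrap and regress phase on s over segments with non-trivial amplitude
  dph <- diff(ph)
  dph <- atan2(sin(dph), cos(dph))
  slope <- sum(dph) / (s[length(s)] - s[1])
  expect_close(abs(slope), 2 * pi / p$wavelength_bl,
               tol = 0.02 * 2 * pi / p$wavelength_bl)
})

test_that("midline reconstruction is inextensible and matches circle geometry", {
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 0.5, 50)
  seq <- midlines_from_bending(fld, p)
  for (i in c(1, 10, length(seq$midlines))) {
    expect_close(arc_length(seq$midlines[[i]]), p$body_length_mm,
                 tol = 1e-9 * p$body_length_mm)
  }
  # straight body
  f0 <- generate_bending_field(wave_params(standing_amp_rad = 0,
                                           travelling_amp_rad = 0), 0.1, 50)
  m0 <- midlines_from_bending(f0, wave_params())$midlines[[1]]
  expect_lt(max(abs(m0[, 2])), 1e-12)
  expect_close(max(m0[, 1]), 30, tol = 1e-9)

  # constant per-segment bending Theta/n -> chord of a circular arc;
  # oracle: chord = 2 R sin(Theta/2), R = L / Theta, for the continuous
  # curve; the polygonal approximation converges at rate (Theta/2n)^2 / 6
  n <- 200
  Theta <- pi / 2
  fld_c <- bending_field(matrix(Theta / n, 1, n), 0,
                         seq(0, 1, length.out = n))
  p_c <- wave_params(n_segments = n)
  m <- midlines_from_bending(fld_c, p_c)$midlines[[1]]
  chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  R <- p_c$body_length_mm / Theta
  expect_close(chord, 2 * R * sin(Theta / 2),
               tol = 2 * R * sin(Theta / 2) * (Theta / (2 * n))^2)
})

test_that("generate -> midlines -> bending_series round trip is exact", {
  p <- wave_presets("compensated")
  fld <- generate_bending_field(p, 1, 100)
  back <- bending_series(midlines_from_bending(fld, p))
  expect_lt(max(abs(back$theta - fld$theta)), 1e-6)
})

test_that("single-frequency fit recovers frequency and amplitude", {
  # noiseless single tone: |Z| = amplitude exactly
  amp <- c(rep(0.02, 25), rep(0.05, 25))
  fld <- tone_field(amp, freq = 2.5, fps = 100, duration = 2)
  fit <- fit_single_frequency(fld)
  expect_close(fit$freq_hz, 2.5, tol = 0.5)   # one spectral bin at 2 s
  expect_lt(max(abs(fit$amplitude - amp)), 1e-6)

  # white noise only: low-power flag and small |Z|
  set.seed(11)
  noise <- matrix(rnorm(200 * 20, 0, 0.05), 200, 20)
  nf <- bending_field(noise, seq(0, 1.99, by = 0.01),
                      seq(0, 1, length.out = 20))
  expect_warning(fitn <- fit_single_frequency(nf), "low-power")
  # noise floor: |Z| ~ sd * sqrt(2/nt); allow generous headroom
  expect_lt(max(fitn$amplitude), 0.05 * sqrt(2 / 200) * 5)
  expect_true(fitn$low_power)
})

test_that("fit rejects records shorter than two periods", {
  fld <- tone_field(rep(0.05, 20), freq = 2.5, fps = 100, duration = 0.5)
  expect_error(fit_single_frequency(fld), "insufficient-data")
})

test_that("standing/travelling decomposition separates the limit cases", {
  s <- seq(0, 1, length.out = 51)
  # pure standing: spatially in-phase profile
  Zs <- complex(real = exp(-(s - 0.3)^2 / 0.02), imaginary = 0)
  ds <- decompose_standing_travelling(Zs)
  expect_lte(mean(ds$travelling_index), 0.1)

  # pure travelling: constant-magnitude rotating phase
  Zt <- exp(-2i * pi * s / 0.5)
  dt <- decompose_standing_travelling(Zt)
  expect_gte(mean(dt$travelling_index), 0.9)

  # 50/50 analytic mixture: |Z+| = a, |Z-| = 3a -> index 0.5 everywhere
  Zm <- exp(2i * pi * 3 * s) + 3 * exp(-2i * pi * 3 * s)
  dm <- decompose_standing_travelling(Zm)
  expect_close(mean(dm$travelling_index), 0.5, tol = 0.1)

  # all-zero input: all-zero output, no error
  d0 <- decompose_standing_travelling(rep(0 + 0i, 20))
  expect_true(all(d0$travelling_index == 0))
})

test_that("travelling index decreases monotonically with stiffening", {
  idx <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(g) {
    p <- wave_params(stiffness_gamma = g)
    fld <- generate_bending_field(p, 2, 100)
    d <- decompose_standing_travelling(fit_single_frequency(fld))
    caudal <- fld$s_frac > p$stiffness_onset + 0.05
    mean(d$travelling_index[caudal])
  }, numeric(1))
  expect_true(all(diff(idx) < 0))
})

test_that("pectoral peak position finds envelope maxima with rostral ties", {
  s <- seq(0, 1, length.out = 51)
  env <- exp(-(s - 0.25)^2 / (2 * 0.08^2))
  expect_close(pectoral_peak_position(env, s), 0.25, tol = 0.01)

  # flat envelope: documented rostral tie-break
  expect_equal(pectoral_peak_position(rep(1, 51), s), 0)

  # all-zero envelope in the window errors
  env0 <- c(rep(0, 26), rep(1, 25))
  expect_error(pectoral_peak_position(env0, s, rostral_window = c(0, 0.4)),
               "undefined-peak")

  # compensated preset peak is caudal to wildtype preset peak
  pk <- vapply(c("flexible", "compensated"), function(cond) {
    p <- wave_presets(cond)
    fld <- generate_bending_field(p, 2, 100)
    pectoral_peak_position(fit_single_frequency(fld))
  }, numeric(1))
  expect_gt(pk["compensated"], pk["flexible"])
})

test_that("peak position recovers the generator value within 0.02 BL", {
  for (pos in c(0.2, 0.25, 0.35)) {
    p <- wave_params(standing_peak_pos = pos)
    fld <- generate_bending_field(p, 2, 100)
    pk <- pectoral_peak_position(fit_single_frequency(fld))
    expect_close(pk, pos, tol = 0.02)
  }
})

test_that("bending field and midline sequence CSV round trips preserve data", {
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 0.2, 50)
  tmp <- tempfile(fileext = ".csv")
  write_bending_field(fld, tmp)
  fld2 <- read_bending_field(tmp)
  expect_equal(fld2$theta, fld$theta, tolerance = 1e-12,
               ignore_attr = TRUE)

  seq <- midlines_from_bending(fld, p)
  tmp2 <- tempfile(fileext = ".csv")
  write_midline_seq(seq, tmp2)
  seq2 <- read_midline_seq(tmp2)
  expect_equal(seq2$midlines[[3]], seq$midlines[[3]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(seq2$fps, seq$fps)
  unlink(c(tmp, tmp2, paste0(c(tmp, tmp2), ".meta.json")))
})

test_that("resampled midlines have equidistant spacing", {
  m <- arc_midline(2.5, n = 37)
  r <- resample_midline(m, 51)
  sp <- sqrt(rowSums(diff(unclass(r))^2))
  expect_lt(diff(range(sp)) / mean(sp), 1e-6)
})
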