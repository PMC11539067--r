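test_that("tail kinematics: straight glide gives zero lateral motion", {
  pts <- lapply(1:50, function(i) cbind(seq(0, 30, length.out = 51) + i * 0.2,
                                        rep(0, 51)))
  seq <- midline_seq(pts, fps = 50, units = "mm")
  tk <- tail_kinematics(seq)
  expect_lt(max(abs(tk$h_mm)), 1e-9)
  expect_lt(max(abs(tk$hdot_mm_s)), 1e-9)
  expect_equal(steady_speed(tk)$steady_speed_bl_s, 0)
})

test_that("tail kinematics: sinusoidal tail heave matches the derivative oracle", {
  # rigid straight body whose tail end oscillates: max|hdot| = 2*pi*f*A
  A <- 2; f <- 2; fps <- 200
  t <- seq(0, 2 - 1 / fps, by = 1 / fps)
  pts <- lapply(t, function(tt) {
    y_tail <- A * sin(2 * pi * f * tt)
    cbind(seq(0, 30, length.out = 51),
          seq(0, y_tail, length.out = 51))
  })
  seq <- midline_seq(pts, fps = fps, units = "mm")
  tk <- tail_kinematics(seq, recoil = FALSE)
  expect_close(max(abs(tk$hdot_mm_s)), 2 * pi * f * A,
               tol = 0.02 * 2 * pi * f * A)
})

test_that("doubling the standing amplitude raises RMS tail velocity", {
  p1 <- wave_presets("compensated")
  p2 <- p1
  p2$standing_amp_rad <- 2 * p1$standing_amp_rad
  rms <- vapply(list(p1, p2), function(p) {
    fld <- generate_bending_field(p, 2, 100)
    tk <- tail_kinematics(midlines_from_bending(fld, p))
    sqrt(mean(tk$hdot_mm_s^2))
  }, numeric(1))
  expect_gt(rms[2], rms[1])
})

test_that("mean thrust obeys the elongated-body signs and decreases in U", {
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 2, 100)
  tk <- tail_kinematics(midlines_from_bending(fld, p))
  cfg <- propulsion_config()
  t0 <- mean_thrust(tk, 0, cfg)
  expect_gte(t0, 0)
  grid <- seq(0, 5, by = 0.25)
  tu <- vapply(grid, function(u) mean_thrust(tk, u, cfg), numeric(1))
  expect_true(all(diff(tu) < 0))

  # no undulation: thrust never positive at positive speed
  pts <- lapply(1:30, function(i) cbind(seq(0, 30, length.out = 51),
                                        rep(0, 51)))
  tk0 <- tail_kinematics(midline_seq(pts, fps = 50, units = "mm"))
  expect_lte(mean_thrust(tk0, 1, cfg), 0)
  expect_equal(mean_thrust(tk0, 0, cfg), 0)
})

test_that("steady speeds of the shipped presets reproduce the condition ordering", {
  cfg <- propulsion_config()
  speeds <- vapply(wave_presets("all"), function(p) {
    fld <- generate_bending_field(p, 2, 100)
    steady_speed(tail_kinematics(midlines_from_bending(fld, p)), cfg)$steady_speed_bl_s
  }, numeric(1))
  expect_gt(speeds["flexible"], speeds["stiff"])
  expect_gt(speeds["compensated"], speeds["stiff"])
  expect_lt(abs(speeds["compensated"] - speeds["flexible"]),
            0.15 * speeds["flexible"])
})

test_that("steady speed is invariant to rigid motion of the fish", {
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 2, 100)
  seq <- midlines_from_bending(fld, p)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- midline_seq(lapply(seq$midlines,
                              function(m) sweep(m %*% R, 2, c(55, -20), "+")),
                       fps = seq$fps, units = "mm")
  u1 <- steady_speed(tail_kinematics(seq))$steady_speed_bl_s
  u2 <- steady_speed(tail_kinematics(moved))$steady_speed_bl_s
  expect_close(u2, u1, tol = 1e-6 * u1)
})

test_that("steady speed errors when the bracket cannot contain the root", {
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 2, 100)
  tk <- tail_kinematics(midlines_from_bending(fld, p))
  cfg <- propulsion_config(speed_bracket_bl_s = c(0, 0.01))
  expect_error(steady_speed(tk, cfg), "bracket")
})

test_that("compare_conditions is deterministic without jitter and ordered with it", {
  cfg <- propulsion_config()
  tab0 <- compare_conditions(n_noise_reps = 1, jitter_cv = 0, seed = 5,
                             cfg = cfg)
  direct <- vapply(wave_presets("all"), function(p) {
    fld <- generate_bending_field(p, 2, 100)
    steady_speed(tail_kinematics(midlines_from_bending(fld, p)), cfg)$steady_speed_bl_s
  }, numeric(1))
  expect_equal(tab0$speed_bl_s, unname(direct[tab0$condition]),
               tolerance = 1e-10)

  tab <- compare_conditions(n_noise_reps = 8, jitter_cv = 0.1, seed = 2,
                            cfg = cfg)
  med <- tapply(tab$speed_bl_s, tab$condition, stats::median, na.rm = TRUE)
  expect_lt(med["stiff"], med["compensated"])
  expect_lt(med["stiff"], med["flexible"])
})

test_that("flexible vs stiff speed distributions separate under a permutation test", {
  tab <- compare_conditions(n_noise_reps = 20, jitter_cv = 0.1, seed = 3)
  x <- tab$speed_bl_s[tab$condition == "flexible"]
  y <- tab$speed_bl_s[tab$condition == "stiff"]
  pt <- permutation_test(x, y, n_resamples = 2000, seed = 4)
  expect_lt(pt$p_value, 0.05)
})

test_that("a compensating standing wave exists and its peak lies caudal to wildtype", {
  cs <- compensation_search()
  expect_true(any(cs$grid$compensates))
  expect_close(cs$best$speed_bl_s, cs$flexible_speed_bl_s,
               tol = 0.05 * cs$flexible_speed_bl_s)
  expect_gt(cs$best$peak, cs$wildtype_peak_pos)
})
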