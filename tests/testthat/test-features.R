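test_that("tortuosity endpoints and the semicircle oracle hold", {
  expect_equal(tortuosity(straight_midline()), 0)

  # closed loop: head coincides with tail (sampled just short of closure,
  # then forced closed)
  phi <- seq(0, 2 * pi, length.out = 51)
  loop <- cbind(sin(phi), 1 - cos(phi))
  loop[51, ] <- loop[1, ]
  expect_equal(tortuosity(loop), 1)

  expect_close(tortuosity(arc_midline(pi, n = 2001)), (pi - 2) / pi, tol = 1e-6)
  expect_error(tortuosity(matrix(c(0, 0, 0, 0), 2, 2)), "invalid-midline")
})

test_that("tortuosity is invariant under rigid motion and scale", {
  m <- arc_midline(1.7, n = 41)
  base <- tortuosity(m)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(unclass(m) %*% R * 3.7, 2, c(12, -5), "+")
  expect_close(tortuosity(moved), base, tol = 1e-12)
})

test_that("velocity series matches uniform and circular motion oracles", {
  fps <- 100
  t <- seq(0, 2, by = 1 / fps)
  v <- 35
  tr <- trajectory(t, v * t, rep(0, length(t)), fps)
  vs <- velocity_series(tr)
  expect_close(stats::median(vs$speed), v, tol = 1e-9)
  expect_close(stats::median(vs$thrust), v, tol = 1e-9)

  # stationary
  tr0 <- trajectory(t, rep(3, length(t)), rep(4, length(t)), fps)
  vs0 <- velocity_series(tr0)
  expect_true(all(vs0$speed == 0))

  # circular motion: speed = R * omega
  R <- 40; omega <- 2
  trc <- trajectory(t, R * cos(omega * t), R * sin(omega * t), fps)
  vsc <- velocity_series(trc)
  mid <- seq(10, length(t) - 10)
  expect_close(stats::median(vsc$speed[mid]), R * omega,
               tol = 0.02 * R * omega)

  expect_error(velocity_series(trajectory(c(0, 0.1, 0.05), 1:3, 1:3, 10)))
})

test_that("bending angle matches the chord oracle and preset ordering", {
  expect_equal(max_bending_angle(straight_midline()), 0)

  # circular arc of total turning Theta: chords of the first and last
  # thirds subtend Theta/3 each, separated by Theta * 2/3 on average;
  # the angle between the two chords is exactly 2/3 * Theta
  Theta <- 1.2
  m <- arc_midline(Theta, n = 61)
  expect_close(max_bending_angle(m), 2 / 3 * Theta, tol = 1e-6)

  angles <- vapply(c("stiff", "compensated"), function(cond) {
    p <- wave_presets(cond)
    fld <- generate_bending_field(p, 2, 100)
    stats::median(bending_angle_series(midlines_from_bending(fld, p)))
  }, numeric(1))
  expect_gt(angles["compensated"], angles["stiff"])
})

test_that("occupancy map conserves mass at 100 percent", {
  spec <- arena_spec()
  tr <- simulate_arena_track(spec, "mutant", duration_s = 30, fps = 10,
                             seed = 6)
  om <- occupancy_map(tr, spec)
  expect_close(sum(om$pct), 100, tol = 1e-9)
  om2 <- occupancy_map(tr, spec, n_bins = c(7, 3))
  expect_close(sum(om2$pct), 100, tol = 1e-9)

  # stationary trajectory: a single bin holds everything
  trs <- trajectory((0:99) / 10, rep(150, 100), rep(50, 100), 10)
  oms <- occupancy_map(trs, spec)
  expect_equal(max(oms$pct), 100)
  expect_equal(sum(oms$pct > 0), 1)

  expect_error(occupancy_map(trajectory(numeric(0), numeric(0),
                                        numeric(0), 10), spec))
})

test_that("uniform positions give multinomial-consistent occupancy deviations", {
  spec <- arena_spec()
  n_bins <- c(10, 5)
  n <- 10000
  p0 <- 100 / prod(n_bins)
  set.seed(17)
  max_dev <- vapply(1:100, function(i) {
    tr <- trajectory((seq_len(n) - 1) / 10,
                     runif(n, 0, spec$width_mm),
                     runif(n, 0, spec$height_mm), 10)
    max(abs(occupancy_map(tr, spec, n_bins)$pct - p0))
  }, numeric(1))
  # multinomial oracle: per-bin sd of the percentage estimate
  sd_bin <- 100 * sqrt((p0 / 100) * (1 - p0 / 100) / n)
  # the max over 50 bins across 100 runs should stay within ~5 sd
  expect_lt(max(max_dev), 5 * sd_bin)
  expect_gt(mean(max_dev), sd_bin)   # and is not degenerate
})

test_that("centre occupancy hits its limit cases and preset ordering", {
  spec <- arena_spec()
  t <- (0:99) / 10
  inside <- trajectory(t, runif(100, 0, 300), rep(50, 100), 10)
  expect_equal(centre_occupancy(inside, spec), 1)
  outside <- trajectory(t, runif(100, 0, 300), rep(2, 100), 10)
  expect_equal(centre_occupancy(outside, spec), 0)
})

test_that("escape time series aligns to the stimulus and bands collapse for n = 1", {
  esc <- simulate_escape_sequence(duration_s = 0.35, fps = 468,
                                  stim_time_s = 0.1)
  single <- escape_timeseries(list(esc), stim_times = 0.1, n_boot = 50)
  expect_equal(single$tortuosity$median, single$tortuosity$lower)
  expect_equal(single$tortuosity$median, single$tortuosity$upper)

  escs <- lapply(1:4, function(i)
    simulate_escape_sequence(duration_s = 0.35, fps = 468,
                             stim_time_s = 0.1,
                             peak_curvature_total = 4 + 0.2 * i))
  multi <- escape_timeseries(escs, stim_times = 0.1, n_boot = 100)
  peak_t <- multi$time_s[which.max(multi$tortuosity$median)]
  expect_gt(peak_t, 0)

  # straight-swimming control: tortuosity ~ 0 throughout
  ctrl <- lapply(1:3, function(i) {
    pts <- lapply(1:100, function(k)
      cbind(seq(0, 30, length.out = 51) + 0.1 * k, rep(0, 51)))
    midline_seq(pts, fps = 468, units = "mm")
  })
  flat <- escape_timeseries(ctrl, stim_times = 0.1, n_boot = 50)
  expect_lt(max(flat$tortuosity$median), 1e-9)
})
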