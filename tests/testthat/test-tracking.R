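stack1 <- small_stack(duration = 1, fps = 25, seed = 7)

test_that("segmentation recovers the rendered silhouette", {
  cfg <- track_config()
  mask <- segment_fish(stack1$frames[[1]], cfg)
  truth <- stack1$masks[[1]]
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)

  # inverted polarity with the matching flag gives the same result
  inv <- 255 - stack1$frames[[1]]
  mask_inv <- segment_fish(inv, track_config(polarity = "bright-fish"))
  iou_inv <- sum(mask_inv & truth) / sum(mask_inv | truth)
  expect_close(iou_inv, iou, tol = 0.02)

  blank <- matrix(200L, 60, 80)
  expect_error(segment_fish(blank, cfg), "no-fish")
})

test_that("midline extraction matches geometry oracles", {
  cfg <- track_config()
  # straight fish: endpoint distance ~ body pixel length
  straight <- midline_seq(lapply(1:3, function(i)
    cbind(seq(0, 30, length.out = 51), rep(0, 51))), fps = 25, units = "mm")
  stf <- render_frames(straight, px_per_mm = 5, bg_noise_sd = 2, seed = 1)
  ml <- extract_midline(segment_fish(stf$frames[[1]], cfg), cfg)
  span <- sqrt(sum((ml[nrow(ml), ] - ml[1, ])^2))
  expect_close(span, 30 * 5, tol = 0.05 * 30 * 5)

  # semicircular fish: tortuosity of the recovered midline ~ (pi-2)/pi
  semi <- midline_seq(list(arc_midline(pi, n = 51, L = 30),
                           arc_midline(pi, n = 51, L = 30)), fps = 25,
                      units = "mm")
  ssf <- render_frames(semi, px_per_mm = 5, bg_noise_sd = 2, seed = 2)
  ml2 <- extract_midline(segment_fish(ssf$frames[[1]], cfg), cfg)
  expect_close(tortuosity(ml2), (pi - 2) / pi, tol = 0.05)

  # resampled spacing is equidistant in arc length (checked on the
  # straight fish, where chords equal arc increments)
  sp <- sqrt(rowSums(diff(unclass(ml))^2))
  expect_lt(diff(range(sp)) / mean(sp), 1e-6)
})

test_that("head orientation follows motion and stays consistent", {
  # forward-swimming synthetic sequence: translate body-frame midlines
  p <- wave_presets("flexible")
  fld <- generate_bending_field(p, 2, 50)
  seq0 <- midlines_from_bending(fld, p)
  v <- 20  # mm/s forward
  pts <- lapply(seq_along(seq0$midlines), function(i) {
    m <- seq0$midlines[[i]]
    # head leads: fish moves towards -x in body frame coordinates
    cbind(-m[, 1] + v * (i - 1) / 50, m[, 2])
  })
  fwd <- midline_seq(pts, fps = 50, units = "mm")
  st <- render_frames(fwd, px_per_mm = 4, seed = 5)
  res <- track_stack(st, track_config())
  gm <- st$ground_truth$midlines_mm
  ok <- vapply(seq_along(gm), function(i) {
    sum((res$seq$midlines[[i]][1, ] - gm[[i]][1, ])^2) <
      sum((res$seq$midlines[[i]][1, ] - gm[[i]][51, ])^2)
  }, logical(1))
  expect_gte(mean(ok), 0.99)

  # no single-frame orientation flips
  heads <- t(vapply(res$seq$midlines, function(m) m[1, ], numeric(2)))
  tails <- t(vapply(res$seq$midlines, function(m) m[51, ], numeric(2)))
  jump <- sqrt(rowSums((heads[-1, ] - heads[-nrow(heads), ])^2))
  flip_dist <- sqrt(rowSums((heads[-1, ] - tails[-nrow(tails), ])^2))
  expect_true(all(jump < flip_dist))
})

test_that("stationary symmetric body is flagged and carried forward", {
  bar <- lapply(1:6, function(i) cbind(seq(10, 40, length.out = 21),
                                       rep(10, 21)))
  traj <- trajectory((0:5) / 10, rep(25, 6), rep(10, 6), 10)
  ori <- orient_head(bar, traj, fps = 10)
  expect_true(all(ori$flagged))
  expect_equal(length(unique(ori$flipped)), 1)  # one consistent choice
})

test_that("track_stack composes, flags failures, and converts units", {
  res <- track_stack(stack1, track_config())
  expect_s3_class(res$seq, "midline_seq")
  expect_equal(res$seq$units, "mm")
  expect_equal(nrow(res$qc), length(stack1$frames))
  expect_true(all(res$qc$ok))

  # inject blank frames: flagged but interpolated
  frames2 <- stack1$frames
  frames2[[5]] <- matrix(200L, nrow(frames2[[5]]), ncol(frames2[[5]]))
  res2 <- track_stack(frames2, track_config(), fps = 25,
                      scale_px_per_mm = stack1$px_per_mm)
  expect_false(res2$qc$ok[5])
  expect_equal(sum(!res2$qc$ok), 1)

  # too many failures abort with a QC report
  frames3 <- lapply(stack1$frames, function(f)
    matrix(200L, nrow(f), ncol(f)))
  expect_error(track_stack(frames3, track_config(), fps = 25),
               "aborted")
})

test_that("tracked midlines recover tortuosity within the error budget", {
  res <- track_stack(stack1, track_config())
  tt <- vapply(res$seq$midlines, tortuosity, numeric(1))
  tg <- vapply(stack1$ground_truth$midlines_mm, tortuosity, numeric(1))
  expect_lt(sqrt(mean((tt - tg)^2)), 0.03)
})
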