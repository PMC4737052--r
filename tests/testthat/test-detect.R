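test_that("static video triggers no detection anywhere", {
  det <- detect_motion(static_video(n = 4))
  expect_length(det$maps, 3L)
  expect_false(any(vapply(det$maps, function(m) any(m$detected), logical(1))))
  expect_error(detect_motion(static_video(n = 1)), "two frames")
})

test_that("a translating bright square is detected with rightward direction", {
  v <- moving_square_video(velocity = c(40, 0), duration = 0.3)
  det <- detect_motion(v)
  grid <- det$grid
  tr <- attr(v, "truth")
  for (t in c(3, 7, 11)) {
    m <- det$maps[[t]]
    ctr <- tr$centers[[t + 1]]
    half <- tr$side / 2
    cx <- grid$centers_x[m$k + 1]
    cy <- grid$centers_y[m$l + 1]
    # For horizontal motion only the vertical (motion-normal) sides of the
    # square change the image; blocks whose window sits on them must fire.
    # Blocks deep inside see uniform content and blocks on the horizontal
    # sides see an edge parallel to the motion (aperture), so the expected
    # set is the motion-normal boundary neighborhood.
    vert_edge <- pmin(abs(cx - (ctr[1] - half)),
                      abs(cx - (ctr[1] + half))) <= 4 &
      abs(cy - ctr[2]) <= half - 2
    background <- abs(cy - ctr[2]) > half + 16
    expect_gt(sum(vert_edge), 3)
    expect_true(all(m$detected[vert_edge]))
    expect_false(any(m$detected[background]))
    err <- ang_diff(m$theta_hat[m$detected & vert_edge], 0)
    expect_true(all(err <= pi / 8))
  }
})

test_that("cardinal motions recover the four cardinal directions", {
  cases <- list(c(40, 0), c(0, 40), c(-40, 0), c(0, -40))
  for (vel in cases) {
    v <- moving_edge_video("on", vel, duration = 0.2)
    det <- detect_motion(v)
    m <- det$maps[[3]]
    expect_gt(sum(m$detected), 10)
    truth <- atan2(vel[2], vel[1]) %% (2 * pi)
    expect_true(all(ang_diff(m$theta_hat[m$detected], truth) <= pi / 8))
  }
})

test_that("detection set is preserved under 5-fold contrast scaling", {
  v <- moving_square_video(velocity = c(40, 0), duration = 0.2)
  vlo <- degrade(v, contrast_factor = 0.2, mean_shift = 0)
  # parameters (eps, threshold) held fixed across the contrast sweep
  d1 <- detect_motion(v, pm_config(eps = 0))
  d2 <- detect_motion(vlo, pm_config(eps = 0))
  for (t in seq_along(d1$maps)) {
    expect_identical(d1$maps[[t]]$detected, d2$maps[[t]]$detected)
    expect_equal(d1$maps[[t]]$pmi, d2$maps[[t]]$pmi, tolerance = 1e-12)
  }
  # with the (small) default eps kept fixed the sets agree up to blocks
  # sitting exactly at the threshold
  d3 <- detect_motion(v)  # default eps resolved on the full-contrast video
  d4 <- detect_motion(vlo, pm_config(eps = d3$eps,
                                     threshold = d3$threshold))
  agree <- mapply(function(a, b) mean(a$detected == b$detected),
                  d3$maps, d4$maps)
  expect_gte(min(agree), 0.9)
})

test_that("PMI contrast ratio: exactly 1 at eps = 0, >= 0.5 at default eps", {
  v <- moving_edge_video("on", c(40, 0), duration = 0.2)
  vlo <- degrade(v, contrast_factor = 0.2, mean_shift = 0)

  ratio_with_eps <- function(eps) {
    d1 <- detect_motion(v, pm_config(eps = eps))
    d2 <- detect_motion(vlo, pm_config(eps = eps))
    r <- c()
    for (t in seq_along(d1$maps)) {
      sel <- d1$maps[[t]]$detected
      r <- c(r, d2$maps[[t]]$pmi[sel] / d1$maps[[t]]$pmi[sel])
    }
    r
  }
  r0 <- ratio_with_eps(0)
  expect_equal(r0, rep(1, length(r0)), tolerance = 1e-10)

  eps_def <- default_epsilon(block_stft(v$frames[[1]],
                                        make_block_grid(64, 64, 6),
                                        make_gaussian_window(4, 32)))
  expect_gte(mean(ratio_with_eps(eps_def)), 0.5)
})

test_that("texture velocity rotated by 90 degrees rotates the readout", {
  vx <- translating_texture_video(seed = 3, velocity = c(30, 0),
                                  duration = 0.2)
  vy <- translating_texture_video(seed = 3, velocity = c(0, 30),
                                  duration = 0.2)
  mx <- detect_motion(vx)$maps[[3]]
  my <- detect_motion(vy)$maps[[3]]
  sel <- mx$detected & my$detected
  expect_gt(sum(sel), 50)
  shift <- (my$theta_hat[sel] - mx$theta_hat[sel]) %% (2 * pi)
  # each readout is quantized to pi/16 angle bins, so allow pi/4 per block
  expect_lt(ang_diff(median(shift), pi / 2), pi / 16 + 1e-9)
  expect_gt(mean(ang_diff(shift, pi / 2) <= pi / 4), 0.95)
})

test_that("auto threshold follows the plane-PMI rule", {
  plan <- radon_plan(32, 16)
  thr <- auto_threshold(plan)
  vals <- vapply((0:31) * 2 * pi / 32, function(p) {
    plane_pmi(10 * cos(p), 10 * sin(p), plan)
  }, numeric(1))
  expect_equal(thr, 0.6 * median(vals))
  # the noisy-video variant raises it by 60%
  det <- detect_motion(static_video(n = 2),
                       pm_config(threshold_scale = 1.6))
  expect_equal(det$threshold, 1.6 * thr)
})

test_that("segmentation masks cover the moving square and only it", {
  v <- moving_square_video(velocity = c(40, 0), duration = 0.24)
  seg <- segment_motion(v)
  tr <- attr(v, "truth")
  for (t in seq_along(seg$masks)) {
    truth <- tr$masks[[t + 1]]
    expect_gte(sum(seg$masks[[t]] & truth) / sum(truth), 0.9)
    # refinement only removes area
    expect_false(any(seg$masks[[t]] & !seg$coarse_masks[[t]]))
  }
  s0 <- segment_motion(static_video(n = 3))
  expect_false(any(vapply(s0$masks, any, logical(1))))
})

test_that("overlay renderer paints arrows only at detected blocks", {
  v <- moving_square_video(velocity = c(40, 0), duration = 0.2)
  det <- detect_motion(v)
  ov <- render_motion_overlay(v, det)
  expect_length(ov, length(det$maps))
  changed <- ov[[3]] != v$frames[[4]]
  expect_gt(sum(changed), 0)
  # all painted pixels lie near detected block centers
  grid <- det$grid
  m <- det$maps[[3]]
  idx <- which(changed, arr.ind = TRUE)
  cx <- grid$centers_x[m$k[m$detected] + 1]
  cy <- grid$centers_y[m$l[m$detected] + 1]
  near <- vapply(seq_len(nrow(idx)), function(i) {
    any(abs(idx[i, 2] - cx) <= 8 & abs(idx[i, 1] - cy) <= 8)
  }, logical(1))
  expect_true(all(near))
})
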