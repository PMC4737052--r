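test_that("block_stft matches the direct double-sum oracle", {
  set.seed(21)
  fr <- matrix(runif(40 * 40), 40, 40)

  for (case in list(list(M = 8, sigma = 2, center = c(11, 11)),
                    list(M = 8, sigma = 2, center = c(1, 1)),      # padded
                    list(M = 32, sigma = 4, center = c(21, 21)))) {
    grid <- make_block_grid(40, 40, 10)
    win <- make_gaussian_window(case$sigma, case$M)
    S <- block_stft(fr, grid, win)
    ki <- which(grid$centers_x == case$center[1])
    li <- which(grid$centers_y == case$center[2])
    ref <- oracle_block_dft(fr, case$center, case$sigma, case$M)
    expect_lt(max(Mod(S[, , ki, li] - ref)) / max(Mod(ref)), 1e-9)
  }
})

test_that("block_stft of a constant frame is the window transform", {
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, 32)
  S <- block_stft(matrix(0.7, 64, 64), grid, win)
  # interior block: spectrum = 0.7 * DFT(window), real and point-symmetric
  Z <- S[, , 6, 6]
  expect_lt(max(abs(Im(Z))), 1e-9 * max(Mod(Z)))
  expect_equal(Re(Z[17, 17]), 0.7 * sum(win$weights), tolerance = 1e-12)
  # linearity in the input scale
  S2 <- block_stft(matrix(1.4, 64, 64), grid, win)
  expect_equal(2 * S[, , 6, 6], S2[, , 6, 6], tolerance = 1e-12)
})

test_that("cosine at a grid frequency peaks at its bin with zero phase", {
  M <- 32
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, M)
  m0 <- 5
  xk <- grid$centers_x[6]
  fr <- matrix(cos((2 * pi / M) * m0 * ((1:64) - xk)),
               64, 64, byrow = TRUE)
  S <- block_stft(fr, grid, win)
  A <- Mod(S[, , 6, 6])
  pk <- which(A == max(A), arr.ind = TRUE)
  expect_setequal(pk[, "col"], bin_of(c(-m0, m0), M))
  expect_true(all(pk[, "row"] == bin_of(0, M)))
  expect_lt(abs(Arg(S[bin_of(0, M), bin_of(m0, M), 6, 6])), 1e-8)
})

test_that("translation shifts the phase by -omega * s", {
  M <- 32
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, M)
  m0 <- 4
  omega <- (2 * pi / M) * m0
  s_px <- 1.3
  mk <- function(shift) {
    matrix(0.5 + 0.5 * cos(omega * ((1:64) - shift)), 64, 64, byrow = TRUE)
  }
  S0 <- block_stft(mk(0), grid, win)
  S1 <- block_stft(mk(s_px), grid, win)
  dphi <- Arg(S1[bin_of(0, M), bin_of(m0, M), 6, 6]) -
    Arg(S0[bin_of(0, M), bin_of(m0, M), 6, 6])
  # error bounded by the window's spectral leakage
  expect_equal(wrap_angle(dphi), -omega * s_px, tolerance = 0.01)
})

test_that("phase derivative is zero for static video and tracks drift", {
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, 32)
  fr <- matrix(runif(64 * 64), 64, 64)
  sp <- lapply(list(fr, fr, fr), block_stft, grid = grid, window = win)
  for (method in c("wrapped_difference", "volterra")) {
    d <- phase_time_derivative(sp, method = method, dt = 0.02)
    expect_length(d, 2L)
    expect_true(all(abs(d[[1]]) < 1e-8))
  }

  # drifting full-field sinusoid: derivative at its bin is -omega * v
  m0 <- 4; v <- 10; fs <- 50
  omega <- (2 * pi / 32) * m0
  vid <- drifting_grating_video(omega = omega, velocity = v,
                                size = c(64, 64), duration = 0.1, fs = fs)
  sp2 <- lapply(vid$frames[1:2], block_stft, grid = grid, window = win)
  d2 <- phase_time_derivative(sp2, dt = 1 / fs)[[1]]
  expect_equal(d2[bin_of(0, 32), bin_of(m0, 32), 6, 6], -omega * v,
               tolerance = 0.02)

  # intensity scaling leaves the phase derivative unchanged
  sp3 <- lapply(vid$frames[1:2],
                function(f) block_stft(3.7 * f, grid, win))
  d3 <- phase_time_derivative(sp3, dt = 1 / fs)[[1]]
  # exact in exact arithmetic; numerically the phase of near-cancelled
  # (vanishing-amplitude) bins is ill-conditioned, so compare where the
  # amplitude is meaningful
  A2 <- attr(d2, "amplitude")
  big <- A2 > 1e-6 * max(A2)
  expect_lt(max(abs(d3[big] - d2[big])), 1e-8 * max(abs(d2)))

  expect_error(phase_time_derivative(sp2[1], dt = 0.02), "two time samples")
})

test_that("wrapped difference and volterra agree on smooth inputs", {
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, 32)
  vid <- drifting_grating_video(omega = 2 * pi / 32 * 3, velocity = 6,
                                size = c(64, 64), duration = 0.1, fs = 50)
  sp <- lapply(vid$frames[1:3], block_stft, grid = grid, window = win)
  dw <- phase_time_derivative(sp, "wrapped_difference", dt = 0.02)[[1]]
  dv <- phase_time_derivative(sp, "volterra", dt = 0.02)[[1]]
  A <- attr(dw, "amplitude")
  big <- A > 0.2 * max(A)  # compare only where the phase is informative
  expect_lt(max(abs(dw[big] - dv[big])), 0.05 * max(abs(dw[big])))
})

test_that("volterra quotient is exact, scale-invariant and O(dt^2)", {
  expect_identical(volterra_phase_derivative(1, 0, 0, 1), 1)
  expect_identical(volterra_phase_derivative(0, 0, 1, 1), 0)

  a <- 0.3; b <- -1.2; da <- 0.7; db <- 0.4
  expect_equal(volterra_phase_derivative(5 * a, 5 * b, 5 * da, 5 * db),
               volterra_phase_derivative(a, b, da, db))

  # sampled spiral z(t) = (1 + 0.3 t) e^{i (2 t + 0.5 sin t)}: compare with a
  # centered difference of the unwrapped atan2 phase
  err_at <- function(dt) {
    t <- seq(0, 2, by = dt)
    z <- (1 + 0.3 * t) * exp(1i * (2 * t + 0.5 * sin(t)))
    a <- Re(z); b <- Im(z)
    i <- 2:(length(t) - 1)
    da <- (a[i + 1] - a[i - 1]) / (2 * dt)
    db <- (b[i + 1] - b[i - 1]) / (2 * dt)
    est <- volterra_phase_derivative(a[i], b[i], da, db)
    truth <- 2 + 0.5 * cos(t[i])
    max(abs(est - truth))
  }
  e1 <- err_at(0.01)
  e2 <- err_at(0.005)
  expect_gt(e1 / e2, 3)  # halving dt shrinks the error ~4x
})

test_that("denoising rescales by relative amplitude", {
  M <- 8
  f <- matrix(rnorm(M * M), M, M)
  A <- matrix(2, M, M)
  expect_equal(denoise_phase_change(f, A, 0), f)          # uniform, eps = 0

  A2 <- A; A2[3, 5] <- 0
  d2 <- denoise_phase_change(f, A2, 0)
  expect_identical(d2[3, 5], 0)                            # zero-amp bin

  expect_lt(max(abs(denoise_phase_change(f, A, 1e9))), 1e-8)  # eps -> Inf
  expect_error(denoise_phase_change(f, A, -1), "nonnegative")

  # empty block (all-zero amplitude) stays finite
  expect_true(all(denoise_phase_change(f * 0, A * 0, 0) == 0))
})

test_that("edge phase-change fields are dominated by the motion plane", {
  fs <- 50
  v <- moving_edge_video("on", c(40, 0), size = c(64, 64),
                         duration = 0.3, fs = fs)
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, 32)
  sp <- lapply(v$frames[5:6], block_stft, grid = grid, window = win)
  d <- phase_time_derivative(sp, dt = 1 / fs)[[1]]
  A <- attr(d, "amplitude")
  pos <- attr(v, "truth")$positions[6]
  crossed <- which(abs(grid$centers_x - pos) < 8)
  expect_gt(length(crossed), 1)
  for (ki in crossed) {
    for (li in c(4, 6, 8)) {
      fit <- fit_phase_plane(d[, , ki, li], weights = A[, , ki, li])
      expect_gt(fit$r2, 0.8)
      expect_gt(fit$vx, 0)  # rightward
    }
  }
})

test_that("drifting gratings are tuned to their own frequency bin", {
  grid <- make_block_grid(64, 64, 6)
  win <- make_gaussian_window(4, 32)
  for (m0 in c(3, 5, 7)) {
    vid <- drifting_grating_video(omega = 2 * pi / 32 * m0, velocity = 8,
                                  size = c(64, 64), duration = 0.1, fs = 50)
    sp <- lapply(vid$frames[1:2], block_stft, grid = grid, window = win)
    d <- phase_time_derivative(sp, dt = 1 / 50)[[1]]
    dn <- denoise_phase_change(d, epsilon = default_epsilon(sp[[1]]))
    f <- dn[, , 6, 6]
    pk <- which(abs(f) == max(abs(f)), arr.ind = TRUE)
    expect_setequal(unique(pk[, "col"]),
                    intersect(bin_of(c(-m0, m0), 32), pk[, "col"]))
    expect_true(all(pk[, "row"] == bin_of(0, 32)))
  }
})
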