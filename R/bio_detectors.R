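# Reference elementary motion detectors: the elaborated Reichardt correlator
# and the Barlow-Levick inhibition detector, run on blurred video subsampled
# at the phase detector's block centers.

#' First-order temporal filter
#'
#' Discrete realization of a continuous first-order filter at frame rate
#' `fs`: low-pass `y[t] = alpha x[t] + (1 - alpha) y[t - 1]` with
#' `alpha = 1 - exp(-1 / (fs * tau))` (exact exponential discretization) and
#' zero initial state; high-pass is the complement `x - lowpass(x)`.
#'
#' @param x numeric time series.
#' @param kind `"low_pass"` or `"high_pass"`.
#' @param tau time constant in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @return filtered series of the same length.
#' @export
temporal_filter <- function(x, kind = c("low_pass", "high_pass"), tau, fs) {
  kind <- match.arg(kind)
  stopifnot(tau > 0, fs > 0)
  alpha <- 1 - exp(-1 / (fs * tau))
  lp <- as.numeric(stats::filter(alpha * x, 1 - alpha,
                                 method = "recursive", init = 0))
  if (kind == "low_pass") lp else x - lp
}

#' Elaborated Reichardt detector response
#'
#' Correlation-based motion detector between two spatial samples.  Each input
#' is first high-passed (the front-end high-pass configuration), then fed to
#' a high-pass branch `g1` and a low-pass branch `g2`; the output is the
#' opponent product `(r2 * g1)(r1 * g2) - (r1 * g1)(r2 * g2)`.  The response
#' is antisymmetric under swapping the inputs, identically zero for equal
#' inputs (uniform flicker), and scales quadratically with contrast.
#'
#' @param u1,u2 equal-length time series sampled at two locations (u2 is the
#'   neighbor in the preferred direction).
#' @param tau_hp high-pass time constant in s (default 0.2).
#' @param tau_lp low-pass time constant in s (default 0.3).
#' @param fs frame rate in Hz (default 50).
#' @return signed response time series.
#' @export
reichardt_response <- function(u1, u2, tau_hp = 0.2, tau_lp = 0.3, fs = 50) {
  if (length(u1) != length(u2)) {
    stop("`u1` and `u2` must have equal length", call. = FALSE)
  }
  r1 <- temporal_filter(u1, "high_pass", tau_hp, fs)
  r2 <- temporal_filter(u2, "high_pass", tau_hp, fs)
  h1 <- temporal_filter(r1, "high_pass", tau_hp, fs)
  h2 <- temporal_filter(r2, "high_pass", tau_hp, fs)
  l1 <- temporal_filter(r1, "low_pass", tau_lp, fs)
  l2 <- temporal_filter(r2, "low_pass", tau_lp, fs)
  h2 * l1 - h1 * l2
}

#' Barlow-Levick detector response
#'
#' Inhibition-based motion detector: the high-passed signal from one point is
#' suppressed by the delayed (low-passed, high-passed) signal from its
#' neighbor, `o(u1, u2) = (u1 * g1) - (u2 * g1 * g2)`; the signed output is
#' the opponent pair `o(u1, u2) - o(u2, u1)`.  The response is linear in
#' contrast.
#'
#' @inheritParams reichardt_response
#' @param tau_hp high-pass time constant in s (default 0.25).
#' @return signed response time series.
#' @export
barlow_levick_response <- function(u1, u2, tau_hp = 0.25, tau_lp = 0.3,
                                   fs = 50) {
  if (length(u1) != length(u2)) {
    stop("`u1` and `u2` must have equal length", call. = FALSE)
  }
  half <- function(a, b) {
    temporal_filter(a, "high_pass", tau_hp, fs) -
      temporal_filter(temporal_filter(b, "high_pass", tau_hp, fs),
                      "low_pass", tau_lp, fs)
  }
  half(u1, u2) - half(u2, u1)
}

#' Gaussian blur of a frame
#'
#' Separable Gaussian convolution (kernel truncated at 3 sigma) with border
#' renormalization, used to low-pass frames before subsampling them at block
#' centers.
#'
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  band <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- g[j - i + r + 1]
      K[i, j] <- w / sum(w)
    }
    K
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Grid of biological motion detectors
#'
#' Blurs every frame with a Gaussian of the same `sigma` as the phase
#' detector's window, samples the blurred video at the block centers, and
#' runs horizontal detectors between centers `(k, l)` and `(k + 1, l)` and
#' vertical detectors between `(k, l)` and `(k, l + 1)`.  Every block center
#' carries one (horizontal, vertical) response pair, matching the phase
#' detector's output grid; centers without a right/lower neighbor report 0.
#'
#' @param video a [video_stream()] with >= 2 frames.
#' @param sigma blur standard deviation in pixels.
#' @param b0 center spacing in pixels.
#' @param kind `"reichardt"` or `"barlow_levick"`.
#' @param threshold motion flag threshold on `|response|` (default 2).
#' @param ... further arguments passed to the response function
#'   (time constants, overriding the defaults).
#' @return object of class `detector_grid`: arrays `h`, `v` of dimension
#'   `c(T, K, L)`, logical flag arrays `h_flag`, `v_flag`, and the `grid`.
#' @export
detector_array <- function(video, sigma = 4, b0 = 6,
                           kind = c("reichardt", "barlow_levick"),
                           threshold = 2, ...) {
  kind <- match.arg(kind)
  Tn <- length(video$frames)
  if (Tn < 2L) stop("need at least two frames", call. = FALSE)
  grid <- make_block_grid(video$Px, video$Py, b0)
  ts <- array(0, dim = c(Tn, grid$K, grid$L))
  for (t in seq_len(Tn)) {
    bl <- gaussian_blur(video$frames[[t]], sigma)
    ts[t, , ] <- t(bl[grid$centers_y, grid$centers_x, drop = FALSE])
  }
  resp <- switch(kind,
                 reichardt = function(a, b) {
                   reichardt_response(a, b, fs = video$frame_rate, ...)
                 },
                 barlow_levick = function(a, b) {
                   barlow_levick_response(a, b, fs = video$frame_rate, ...)
                 })
  h <- array(0, dim = c(Tn, grid$K, grid$L))
  v <- array(0, dim = c(Tn, grid$K, grid$L))
  for (li in seq_len(grid$L)) {
    for (ki in seq_len(grid$K)) {
      if (ki < grid$K) h[, ki, li] <- resp(ts[, ki, li], ts[, ki + 1L, li])
      if (li < grid$L) v[, ki, li] <- resp(ts[, ki, li], ts[, ki, li + 1L])
    }
  }
  structure(list(h = h, v = v,
                 h_flag = abs(h) > threshold, v_flag = abs(v) > threshold,
                 grid = grid, kind = kind, threshold = threshold),
            class = "detector_grid")
}
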