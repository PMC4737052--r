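# Seeded, deterministic generators for the synthetic stimuli and
# degradations used throughout the tests: moving ON/OFF edges, translating
# bright squares, drifting sinusoidal gratings, translating random textures,
# and contrast / luminance / noise degradations.

frame_count <- function(duration, fs) {
  n <- round(duration * fs)
  if (n < 2) stop("duration * fs must give at least 2 frames", call. = FALSE)
  as.integer(n)
}

check_size <- function(size) {
  if (length(size) != 2L || any(size < 2)) {
    stop("`size` must be c(Px, Py) with both >= 2", call. = FALSE)
  }
  c(Px = as.integer(size[1]), Py = as.integer(size[2]))
}

#' Moving ON/OFF edge video
#'
#' A straight step edge perpendicular to the motion direction; the bright
#' side trails the advancing front, so a fixed pixel switches dark to bright
#' as the edge passes (ON); the OFF edge is the frame-by-frame complement.
#' The edge position integrates the (constant) velocity and sub-pixel
#' positions are rendered by a linear 1-pixel ramp.
#'
#' @param kind `"on"` or `"off"`.
#' @param velocity `c(vx, vy)` in px/s; the edge is normal to this direction.
#' @param size `c(Px, Py)` in pixels.
#' @param duration length in seconds (`duration * fs >= 2` frames).
#' @param fs frame rate in Hz.
#' @param start initial edge offset along the motion direction; defaults so
#'   the edge sweeps symmetrically through the frame center.
#' @return a [video_stream()]; attribute `"truth"` holds the kind, velocity,
#'   direction angle and per-frame edge positions.
#' @export
moving_edge_video <- function(kind = c("on", "off"), velocity = c(40, 0),
                              size = c(64, 64), duration = 0.5, fs = 50,
                              start = NULL) {
  kind <- match.arg(kind)
  sz <- check_size(size)
  n <- frame_count(duration, fs)
  speed <- sqrt(sum(velocity^2))
  d <- if (speed > 0) velocity / speed else c(1, 0)
  P <- outer(seq_len(sz["Py"]) * d[2], seq_len(sz["Px"]) * d[1], "+")
  p_center <- d[1] * (sz["Px"] + 1) / 2 + d[2] * (sz["Py"] + 1) / 2
  travel <- speed * (n - 1) / fs
  if (is.null(start)) start <- p_center - travel / 2
  pos <- start + speed * (0:(n - 1)) / fs
  frames <- lapply(pos, function(p) {
    f <- pmin(pmax(p - P + 0.5, 0), 1)
    if (kind == "off") f <- 1 - f
    f
  })
  v <- video_stream(frames, fs)
  attr(v, "truth") <- list(kind = kind, velocity = velocity,
                           direction = atan2(d[2], d[1]) %% (2 * pi),
                           positions = pos, projection = P)
  v
}

#' Translating bright square video
#'
#' A square of intensity `fg` on a `bg` background, translating at constant
#' velocity; sub-pixel positions are rendered by linear ramps on all four
#' sides.
#'
#' @param velocity `c(vx, vy)` in px/s.
#' @param size `c(Px, Py)` in pixels.
#' @param side square side in pixels.
#' @param start initial center `c(x, y)`; defaults so the square sweeps
#'   symmetrically through the frame center.
#' @param fg,bg foreground and background intensities in `[0, 1]`.
#' @param duration,fs duration (s) and frame rate (Hz).
#' @return a [video_stream()]; attribute `"truth"` holds the velocity and a
#'   per-frame logical footprint mask.
#' @export
moving_square_video <- function(velocity = c(40, 0), size = c(64, 64),
                                side = 24, start = NULL, fg = 1, bg = 0,
                                duration = 0.5, fs = 50) {
  sz <- check_size(size)
  n <- frame_count(duration, fs)
  travel <- velocity * (n - 1) / fs
  if (is.null(start)) {
    start <- c((sz["Px"] + 1) / 2, (sz["Py"] + 1) / 2) - travel / 2
  }
  xs <- seq_len(sz["Px"])
  ys <- seq_len(sz["Py"])
  frames <- vector("list", n)
  masks <- vector("list", n)
  for (t in seq_len(n)) {
    ctr <- start + velocity * (t - 1) / fs
    bx <- pmin(pmax(pmin(xs - (ctr[1] - side / 2) + 0.5,
                         (ctr[1] + side / 2) - xs + 0.5), 0), 1)
    by <- pmin(pmax(pmin(ys - (ctr[2] - side / 2) + 0.5,
                         (ctr[2] + side / 2) - ys + 0.5), 0), 1)
    box <- outer(by, bx)
    frames[[t]] <- bg + (fg - bg) * box
    masks[[t]] <- box > 0.5
  }
  v <- video_stream(frames, fs)
  attr(v, "truth") <- list(velocity = velocity, masks = masks,
                           centers = lapply(seq_len(n) - 1,
                                            function(t) start + velocity * t / fs),
                           side = side)
  v
}

#' Drifting sinusoidal grating video
#'
#' `u(x, y, t) = mean + (contrast / 2) * cos(omega * (x - v t))`; the
#' temporal frequency at a fixed pixel is `omega * v` rad/s.  A warning is
#' issued when the per-frame phase step reaches pi (temporal aliasing).
#'
#' @param omega spatial frequency in rad/pixel (`|omega| <= pi`).
#' @param velocity drift speed along +x in px/s.
#' @param size,duration,fs as elsewhere.
#' @param contrast peak-to-trough amplitude in `(0, 1]`.
#' @param mean mean luminance.
#' @return a [video_stream()]; attribute `"truth"` holds omega and velocity.
#' @export
drifting_grating_video <- function(omega = pi / 4, velocity = 20,
                                   size = c(64, 64), duration = 0.5, fs = 50,
                                   contrast = 1, mean = 0.5) {
  if (abs(omega) > pi) stop("|omega| must be <= pi rad/pixel", call. = FALSE)
  sz <- check_size(size)
  n <- frame_count(duration, fs)
  if (abs(omega * velocity) / fs >= pi) {
    warning("grating is temporally aliased: |omega * v| / fs >= pi",
            call. = FALSE)
  }
  xs <- seq_len(sz["Px"])
  frames <- lapply(0:(n - 1), function(t) {
    row <- mean + (contrast / 2) * cos(omega * (xs - velocity * t / fs))
    matrix(row, sz["Py"], sz["Px"], byrow = TRUE)
  })
  v <- video_stream(frames, fs)
  attr(v, "truth") <- list(omega = omega, velocity = velocity,
                           contrast = contrast, mean = mean)
  v
}

# Periodic sub-pixel shift of a matrix by (sx, sy) pixels via bilinear
# interpolation (positive shifts move content toward +x / +y).
shift_periodic <- function(img, sx, sy) {
  Py <- nrow(img); Px <- ncol(img)
  x0 <- (seq_len(Px) - 1 - sx) %% Px
  y0 <- (seq_len(Py) - 1 - sy) %% Py
  xi <- floor(x0); fx <- x0 - xi
  yi <- floor(y0); fy <- y0 - yi
  xa <- xi %% Px + 1; xb <- (xi + 1) %% Px + 1
  ya <- yi %% Py + 1; yb <- (yi + 1) %% Py + 1
  A <- img[ya, xa, drop = FALSE]; B <- img[ya, xb, drop = FALSE]
  C <- img[yb, xa, drop = FALSE]; D <- img[yb, xb, drop = FALSE]
  WX <- matrix(fx, Py, Px, byrow = TRUE)
  WY <- matrix(fy, Py, Px)
  (1 - WY) * ((1 - WX) * A + WX * B) + WY * ((1 - WX) * C + WX * D)
}

#' Translating random texture video
#'
#' A seeded uniform random texture translated with periodic wrap-around at
#' sub-pixel accuracy (bilinear interpolation).  Calls with the same seed are
#' bit-identical; the caller's RNG state is untouched.
#'
#' @param seed texture seed.
#' @param velocity `c(vx, vy)` in px/s.
#' @param size,duration,fs as elsewhere.
#' @return a [video_stream()]; attribute `"truth"` holds the seed, velocity
#'   and the base frame.
#' @export
translating_texture_video <- function(seed = 1, velocity = c(30, 0),
                                      size = c(64, 64), duration = 0.5,
                                      fs = 50) {
  sz <- check_size(size)
  n <- frame_count(duration, fs)
  base <- with_seed(seed, matrix(stats::runif(sz["Px"] * sz["Py"]),
                                 sz["Py"], sz["Px"]))
  frames <- lapply(0:(n - 1), function(t) {
    shift_periodic(base, velocity[1] * t / fs, velocity[2] * t / fs)
  })
  v <- video_stream(frames, fs)
  attr(v, "truth") <- list(seed = seed, velocity = velocity, base = base)
  v
}

#' Degrade a video: contrast, luminance, noise
#'
#' Applies the affine map `u -> contrast_factor * u + mean_shift` (which must
#' keep the noiseless video inside `[0, 1]`), then optional seeded additive
#' Gaussian white noise with standard deviation `noise_sigma` times the
#' maximum luminance range (1 on this scale), then clips to `[0, 1]`.  The
#' fraction of clipped pixels is recorded in the `"clipped_fraction"`
#' attribute.  `contrast_factor = 0.2, mean_shift = 0.2` maps `[0, 1]` to
#' `[0.2, 0.4]`; `noise_sigma = 0.05` is 5 percent of the luminance range.
#'
#' @param video a [video_stream()].
#' @param contrast_factor multiplicative contrast in `(0, 1]`.
#' @param mean_shift additive luminance offset.
#' @param noise_sigma noise standard deviation as a fraction of the
#'   luminance range.
#' @param seed noise seed.
#' @return degraded [video_stream()].
#' @export
degrade <- function(video, contrast_factor = 1, mean_shift = 0,
                    noise_sigma = 0, seed = 1) {
  if (!is.numeric(contrast_factor) || contrast_factor <= 0 ||
      contrast_factor > 1) {
    stop("`contrast_factor` must be in (0, 1]", call. = FALSE)
  }
  rng <- range(unlist(lapply(video$frames, range)))
  lo <- contrast_factor * rng[1] + mean_shift
  hi <- contrast_factor * rng[2] + mean_shift
  if (lo < -1e-9 || hi > 1 + 1e-9) {
    stop(sprintf(
      "affine map sends intensities to [%.3f, %.3f], outside [0, 1]",
      lo, hi), call. = FALSE)
  }
  frames <- lapply(video$frames, function(f) contrast_factor * f + mean_shift)
  clipped <- 0
  if (noise_sigma > 0) {
    npix <- video$Px * video$Py
    frames <- with_seed(seed, lapply(frames, function(f) {
      f + matrix(stats::rnorm(npix, sd = noise_sigma), video$Py, video$Px)
    }))
    total <- npix * length(frames)
    nclip <- sum(vapply(frames, function(f) sum(f < 0 | f > 1), numeric(1)))
    clipped <- nclip / total
    frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  }
  out <- video_stream(frames, video$frame_rate)
  attr(out, "truth") <- attr(video, "truth")
  attr(out, "clipped_fraction") <- clipped
  out
}
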