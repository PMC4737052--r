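# The end-to-end phase-based detector: configuration, automatic threshold,
# per-frame motion maps, and coarse-to-fine motion segmentation.

#' Detector configuration
#'
#' Collects the tunable parameters of the phase-based motion detector.
#' `eps = "auto"` resolves to [default_epsilon()] on the first frame's
#' spectra; `threshold = "auto"` resolves to [auto_threshold()] (0.6 times
#' the median PMI of an ideal plane at 10 px/s) times `threshold_scale`.
#' Raise `threshold_scale` to 1.6 for thermal-style noisy inputs.
#'
#' @param sigma Gaussian window standard deviation in pixels.
#' @param M block side in pixels (even).
#' @param b0 spacing between window centers in pixels.
#' @param n_theta number of Radon angles.
#' @param eps denoising constant or `"auto"`.
#' @param threshold PMI detection threshold (rad/s) or `"auto"`.
#' @param threshold_scale multiplier applied to the automatic threshold.
#' @param method phase-derivative method, see [phase_time_derivative()].
#' @return a named list of class `pm_config`.
#' @export
pm_config <- function(sigma = 4, M = 32, b0 = 6, n_theta = 16,
                      eps = "auto", threshold = "auto", threshold_scale = 1,
                      method = "wrapped_difference") {
  structure(list(sigma = sigma, M = M, b0 = b0, n_theta = n_theta,
                 eps = eps, threshold = threshold,
                 threshold_scale = threshold_scale, method = method),
            class = "pm_config")
}

#' Automatic PMI threshold
#'
#' `frac` times the median PMI of an ideal plane field with speed
#' `speed` px/s, the median taken over `n_dir` uniformly spaced motion
#' directions (the PMI of a plane depends mildly on its orientation relative
#' to the discrete angle grid).
#'
#' @param plan a [radon_plan()].
#' @param speed reference speed in px/s (default 10).
#' @param frac fraction of the median plane PMI (default 0.6).
#' @param n_dir number of probe directions.
#' @return threshold in rad/s.
#' @export
auto_threshold <- function(plan, speed = 10, frac = 0.6, n_dir = 32) {
  phis <- (0:(n_dir - 1)) * 2 * pi / n_dir
  vals <- vapply(phis, function(p) {
    plane_pmi(speed * cos(p), speed * sin(p), plan)
  }, numeric(1))
  frac * stats::median(vals)
}

resolve_config <- function(config, first_spectra, plan) {
  eps <- config$eps
  if (identical(eps, "auto")) eps <- default_epsilon(first_spectra)
  thr <- config$threshold
  if (identical(thr, "auto")) thr <- auto_threshold(plan)
  thr <- thr * config$threshold_scale
  list(eps = eps, threshold = thr)
}

#' Phase-based motion detection
#'
#' Runs the full pipeline on a video: block STFT, wrapped temporal phase
#' difference, amplitude denoising, bounded Radon transform, PMI thresholding
#' and direction readout, independently for every block.  One motion map is
#' produced per frame after the first.
#'
#' @param video a [video_stream()] with at least 2 frames.
#' @param config a [pm_config()].
#' @return object of class `motion_maps`: a list with `maps` (one data frame
#'   per frame transition, columns `k`, `l` (0-based block indices), `pmi`,
#'   `alpha`, `theta_hat`, `detected`), the `grid`, and the resolved
#'   `eps` / `threshold`.
#' @export
detect_motion <- function(video, config = pm_config()) {
  if (!inherits(video, "video_stream")) stop("`video` must be a video_stream")
  Tn <- length(video$frames)
  if (Tn < 2L) stop("need at least two frames to detect motion", call. = FALSE)
  grid <- make_block_grid(video$Px, video$Py, config$b0)
  win <- make_gaussian_window(config$sigma, config$M)
  plan <- radon_plan(config$M, config$n_theta)
  dt <- 1 / video$frame_rate

  S_prev <- block_stft(video$frames[[1]], grid, win)
  rc <- resolve_config(config, S_prev, plan)

  nb <- grid$K * grid$L
  kk <- rep(0:(grid$K - 1L), times = grid$L)
  ll <- rep(0:(grid$L - 1L), each = grid$K)
  theta_fac <- factor(plan$theta_id, levels = seq_len(plan$n_theta))
  pos_mask <- plan$rho > 0

  maps <- vector("list", Tn - 1L)
  for (t in 2:Tn) {
    S_cur <- block_stft(video$frames[[t]], grid, win)
    dph <- phase_time_derivative(list(S_prev, S_cur),
                                 method = config$method, dt = dt)[[1]]
    dph <- denoise_phase_change(dph, epsilon = rc$eps)
    Fm <- matrix(as.numeric(dph), config$M^2, nb)[plan$idx, , drop = FALSE]
    Sg <- as.matrix(plan$P %*% Fm)            # bins x blocks
    Rc <- Sg / plan$c
    G <- rowsum(abs(Rc), theta_fac)           # n_theta x blocks
    pmi_v <- apply(G, 2, max)
    ai <- max.col(t(G), ties.method = "first")
    Spos <- rowsum(Rc * pos_mask, theta_fac)
    spos <- Spos[cbind(ai, seq_len(nb))]
    theta_hat <- (pi * (sign(spos) + 1) / 2 + plan$angles[ai]) %% (2 * pi)
    detected <- pmi_v > rc$threshold
    maps[[t - 1L]] <- data.frame(
      k = kk, l = ll, pmi = pmi_v, alpha = plan$angles[ai],
      theta_hat = theta_hat, detected = detected)
    S_prev <- S_cur
  }
  structure(list(maps = maps, grid = grid, eps = rc$eps,
                 threshold = rc$threshold, config = config),
            class = "motion_maps")
}

#' @method print motion_maps
#' @export
print.motion_maps <- function(x, ...) {
  nd <- vapply(x$maps, function(m) sum(m$detected), integer(1))
  cat(sprintf(
    "<motion_maps> %d frames, %d x %d blocks, threshold %.4g rad/s, %s\n",
    length(x$maps), x$grid$K, x$grid$L, x$threshold,
    sprintf("detected blocks per frame: %s", paste(nd, collapse = " "))))
  invisible(x)
}

# Pixel footprint (M x M, clipped to the frame) of the block centered at
# (cx, cy); returns row/col index vectors.
block_footprint <- function(cx, cy, M, Px, Py) {
  xs <- (cx - M / 2):(cx + M / 2 - 1)
  ys <- (cy - M / 2):(cy + M / 2 - 1)
  list(x = xs[xs >= 1 & xs <= Px], y = ys[ys >= 1 & ys <= Py])
}

# PMI of a single M x M block between two frames (used by the segmentation
# refinement at M = 16).
single_block_pmi <- function(frame1, frame2, center, win, plan, eps, dt) {
  M <- win$M
  sh <- fftshift_index(M)
  sp <- function(fr) {
    Z <- stats::fft((extract_block(fr, center, M) * win$weights)[sh, sh])
    Z[sh, sh]
  }
  S1 <- sp(frame1); S2 <- sp(frame2)
  A2 <- Mod(S2)
  d <- wrap_angle(Arg(S2) - Arg(S1)) / dt
  d[Mod(S1) == 0 | A2 == 0] <- 0
  d <- d * (A2 / (mean(A2) + eps))
  pmi(bounded_radon(d, plan))
}

#' Coarse-to-fine motion segmentation
#'
#' Detects salient motion at the full block size (default 32, with a raised
#' threshold), takes the union of the detected blocks' pixel footprints as
#' the coarse mask, then re-tests the boundary blocks with 16 x 16 blocks
#' (`omega0 = 2 pi / 16`).  Boundary areas whose fine-scale test is negative
#' are removed from the mask; refinement only ever removes area, so the
#' refined mask is contained in the coarse one.
#'
#' @param video a [video_stream()].
#' @param config a [pm_config()]; its threshold is interpreted at the
#'   salient-object level.  With `threshold = "auto"` the automatic threshold
#'   is raised by `coarse_scale`.
#' @param refine_M fine block side (default 16; set `NA` to skip refinement).
#' @param coarse_scale multiplier applied to the automatic threshold to reach
#'   the salient-object level (default 2).
#' @return object of class `motion_segmentation`: list with `masks` (logical
#'   `Py` x `Px` matrices, one per frame transition), `coarse_masks`, and the
#'   underlying `detection`.
#' @export
segment_motion <- function(video, config = pm_config(), refine_M = 16,
                           coarse_scale = 2) {
  if (identical(config$threshold, "auto")) {
    config$threshold_scale <- config$threshold_scale * coarse_scale
  }
  det <- detect_motion(video, config)
  grid <- det$grid
  Px <- video$Px; Py <- video$Py
  M <- config$M
  refine <- is.numeric(refine_M) && is.finite(refine_M)
  if (refine) {
    win_f <- make_gaussian_window(config$sigma, refine_M)
    plan_f <- radon_plan(refine_M, config$n_theta)
    thr_f <- auto_threshold(plan_f) * config$threshold_scale / coarse_scale
    dt <- 1 / video$frame_rate
  }
  masks <- vector("list", length(det$maps))
  coarse_masks <- vector("list", length(det$maps))
  for (t in seq_along(det$maps)) {
    mp <- det$maps[[t]]
    dmat <- matrix(mp$detected, grid$K, grid$L)
    mask <- matrix(FALSE, Py, Px)
    for (i in which(mp$detected)) {
      fp <- block_footprint(grid$centers_x[mp$k[i] + 1L],
                            grid$centers_y[mp$l[i] + 1L], M, Px, Py)
      mask[fp$y, fp$x] <- TRUE
    }
    coarse_masks[[t]] <- mask
    if (refine && any(dmat)) {
      # boundary blocks: detected with at least one undetected or missing
      # 4-neighbor in the block grid
      pad <- matrix(FALSE, grid$K + 2L, grid$L + 2L)
      pad[2:(grid$K + 1L), 2:(grid$L + 1L)] <- dmat
      inner <- pad[2:(grid$K + 1L), 2:(grid$L + 1L)]
      nb_all <- pad[1:grid$K, 2:(grid$L + 1L)] &
        pad[3:(grid$K + 2L), 2:(grid$L + 1L)] &
        pad[2:(grid$K + 1L), 1:grid$L] &
        pad[2:(grid$K + 1L), 3:(grid$L + 2L)]
      boundary <- inner & !nb_all
      for (ki in seq_len(grid$K)) {
        for (li in seq_len(grid$L)) {
          if (!boundary[ki, li]) next
          ctr <- c(grid$centers_x[ki], grid$centers_y[li])
          p <- single_block_pmi(video$frames[[t]], video$frames[[t + 1L]],
                                ctr, win_f, plan_f, det$eps, dt)
          if (p <= thr_f) {
            fp <- block_footprint(ctr[1], ctr[2], refine_M, Px, Py)
            mask[fp$y, fp$x] <- FALSE
          }
        }
      }
    }
    masks[[t]] <- mask
  }
  structure(list(masks = masks, coarse_masks = coarse_masks, detection = det),
            class = "motion_segmentation")
}

#' Render motion arrows onto frames
#'
#' Draws a short line segment from each detected block center along its
#' estimated direction, for visual inspection of the detector output.
#'
#' @param video a [video_stream()].
#' @param detection a [detect_motion()] result for this video.
#' @param arrow_len arrow length in pixels.
#' @param value intensity painted on the arrow pixels.
#' @return list of annotated frames (same size as the video frames, one per
#'   motion map).
#' @export
render_motion_overlay <- function(video, detection, arrow_len = 6, value = 1) {
  grid <- detection$grid
  out <- vector("list", length(detection$maps))
  for (t in seq_along(detection$maps)) {
    fr <- video$frames[[t + 1L]]
    mp <- detection$maps[[t]]
    for (i in which(mp$detected)) {
      cx <- grid$centers_x[mp$k[i] + 1L]
      cy <- grid$centers_y[mp$l[i] + 1L]
      s <- seq(0, arrow_len, by = 0.5)
      px <- round(cx + s * cos(mp$theta_hat[i]))
      py <- round(cy + s * sin(mp$theta_hat[i]))
      ok <- px >= 1 & px <= video$Px & py >= 1 & py <= video$Py
      fr[cbind(py[ok], px[ok])] <- value
    }
    out[[t]] <- fr
  }
  out
}
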