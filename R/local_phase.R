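# Per-block windowed 2D FFT (local amplitude/phase on the signed frequency
# grid) and the temporal phase-change field, including the Volterra form of
# the phase derivative and amplitude-based denoising.

#' Block short-space Fourier transform
#'
#' For every block of the grid, multiplies the zero-padded `M` x `M` patch by
#' the Gaussian window and computes the 2D discrete Fourier transform with the
#' spatial origin at the window center, i.e. the value at signed frequency
#' index `(m, n)` is
#' `sum_{dx,dy} u(xk + dx, yl + dy) w(dx, dy) exp(-i w0 (m dx + n dy))`
#' with `w0 = 2 pi / M` and offsets `dx, dy in -M/2, ..., M/2 - 1`.  The
#' center-referencing is achieved by index reordering of the patch (a circular
#' shift placing the center at index 0) before the FFT, which is bit-exact to
#' the double sum.
#'
#' @param frame numeric matrix `frame[y, x]`.
#' @param grid a [make_block_grid()] object.
#' @param window a [make_gaussian_window()] object.
#' @return complex array of dimension `c(M, M, K, L)`; `[n_idx, m_idx, k, l]`
#'   where `n_idx`/`m_idx` index the signed y/x frequencies in ascending
#'   order (DC at `M/2 + 1`) and `k`, `l` are 1-based block indices along x
#'   and y.  Class `local_spectra`, with attributes `M`, `omega0`, `K`, `L`.
#' @export
block_stft <- function(frame, grid, window) {
  if (!inherits(grid, "block_grid")) stop("`grid` must be a block_grid")
  if (!inherits(window, "gaussian_window")) {
    stop("`window` must be a gaussian_window")
  }
  if (nrow(frame) != grid$Py || ncol(frame) != grid$Px) {
    stop("frame dimensions do not match the block grid", call. = FALSE)
  }
  M <- window$M
  sh <- fftshift_index(M)
  W <- window$weights
  S <- array(0i, dim = c(M, M, grid$K, grid$L))
  for (li in seq_len(grid$L)) {
    cy <- grid$centers_y[li]
    for (ki in seq_len(grid$K)) {
      cx <- grid$centers_x[ki]
      wp <- extract_block(frame, c(cx, cy), M) * W
      Z <- stats::fft(wp[sh, sh])
      S[, , ki, li] <- Z[sh, sh]
    }
  }
  structure(S, class = "local_spectra",
            M = M, omega0 = 2 * pi / M, K = grid$K, L = grid$L)
}

#' Temporal derivative of the local phase
#'
#' Given a time-ordered list of [block_stft()] outputs, returns the per-bin
#' phase-change field for each consecutive pair of frames.
#'
#' Methods:
#' * `"wrapped_difference"` (default): `wrap(phi_t - phi_{t-dt}) / dt`, the
#'   wrapped first difference, robust to the 2 pi ambiguity.
#' * `"volterra"`: the quotient form
#'   `(a db/dt - b da/dt) / (a^2 + b^2)` with `a`, `b` the real and imaginary
#'   parts of the spectrum and the temporal derivatives approximated by first
#'   differences (see [volterra_phase_derivative()]).
#'
#' Bins where the amplitude is exactly zero in either frame carry no phase
#' information; their derivative is set to 0.
#'
#' @param spectra list of `local_spectra` arrays, length >= 2, equal shapes.
#' @param method `"wrapped_difference"` or `"volterra"`.
#' @param dt time step in seconds (`1 / frame_rate`).
#' @return list of length `length(spectra) - 1`; element `t` is a real array
#'   shaped like the spectra holding `dphi/dt` (rad/s) between frames `t` and
#'   `t + 1`, with the amplitude of the later frame attached as attribute
#'   `"amplitude"` (used for denoising).
#' @export
phase_time_derivative <- function(spectra,
                                  method = c("wrapped_difference", "volterra"),
                                  dt) {
  method <- match.arg(method)
  if (!is.list(spectra) || length(spectra) < 2L) {
    stop("need at least two time samples of local spectra", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive scalar (seconds)", call. = FALSE)
  }
  out <- vector("list", length(spectra) - 1L)
  for (t in 2:length(spectra)) {
    S1 <- spectra[[t - 1L]]
    S2 <- spectra[[t]]
    if (!identical(dim(S1), dim(S2))) {
      stop("all spectra must have identical dimensions", call. = FALSE)
    }
    A1 <- Mod(S1)
    A2 <- Mod(S2)
    if (method == "wrapped_difference") {
      d <- wrap_angle(Arg(S2) - Arg(S1)) / dt
      d[A1 == 0 | A2 == 0] <- 0
    } else {
      a <- Re(S2); b <- Im(S2)
      da <- (Re(S2) - Re(S1)) / dt
      db <- (Im(S2) - Im(S1)) / dt
      d <- volterra_phase_derivative(a, b, da, db)
    }
    d <- array(as.numeric(d), dim = dim(S2))
    attr(d, "amplitude") <- A2
    out[[t - 1L]] <- d
  }
  out
}

#' Volterra form of the phase derivative
#'
#' The time derivative of `atan2(b, a)` expressed as a second-order Volterra
#' kernel acting on the quadrature pair `(a, b)` and its temporal
#' derivatives: `(a db - b da) / (a^2 + b^2)`.  Returns 0 where
#' `a^2 + b^2 = 0` (phase undefined at zero amplitude).  The quotient is
#' invariant to a common positive scaling of all four inputs.
#'
#' @param a,b real and imaginary parts of the local spectrum value.
#' @param da,db their temporal derivatives (per second).
#' @return phase derivative in rad/s, same shape as the inputs.
#' @export
volterra_phase_derivative <- function(a, b, da, db) {
  den <- a^2 + b^2
  out <- (db * a - da * b)
  zero <- den == 0
  out[!zero] <- out[!zero] / den[!zero]
  out[zero] <- 0
  out
}

#' Amplitude-weighted denoising of a phase-change field
#'
#' Multiplies each bin of the phase-change field by
#' `A(w) / (mean_{D^2}(A) + epsilon)`, where the mean amplitude is taken per
#' block over all `M^2` bins.  This discounts phase-change measurements at
#' low-amplitude bins, where the phase is uninformative and noisy.  With
#' uniform amplitude and `epsilon = 0` the field is unchanged; as
#' `epsilon -> Inf` the field vanishes.
#'
#' @param field real array of `dphi/dt` values; either an `M` x `M` matrix
#'   (single block) or an `c(M, M, K, L)` array as produced by
#'   [phase_time_derivative()].
#' @param amplitude matching array of local amplitudes `A >= 0`.  Defaults to
#'   the `"amplitude"` attribute of `field` if present.
#' @param epsilon nonnegative regularization constant (amplitude units).
#' @return denoised field, same shape and attributes as `field`.
#' @export
denoise_phase_change <- function(field, amplitude = attr(field, "amplitude"),
                                 epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0) {
    stop("`epsilon` must be a nonnegative scalar", call. = FALSE)
  }
  if (is.null(amplitude)) stop("`amplitude` is required", call. = FALSE)
  dm <- dim(field)
  if (!identical(dim(amplitude), dm)) {
    stop("`field` and `amplitude` must have identical dimensions",
         call. = FALSE)
  }
  M2 <- dm[1] * dm[2]
  nb <- prod(dm) / M2
  Fm <- matrix(field, M2, nb)
  Am <- matrix(amplitude, M2, nb)
  meanA <- colMeans(Am)
  den <- meanA + epsilon
  den[den == 0] <- Inf   # empty block: field is zero anyway, multiplier 0
  mult <- sweep(Am, 2, den, "/")
  out <- array(Fm * mult, dim = dm)
  attributes(out) <- attributes(field)
  out
}

#' Default denoising constant
#'
#' `1e-3` times the global mean block amplitude of the supplied spectra
#' (typically the first frame of a video).  Keeps the PMI contrast ratio high
#' at low contrast while suppressing noise in empty blocks.
#'
#' @param spectra a `local_spectra` array.
#' @param scale multiplier of the mean amplitude (default `1e-3`).
#' @return nonnegative scalar epsilon.
#' @export
default_epsilon <- function(spectra, scale = 1e-3) {
  scale * mean(Mod(spectra))
}

#' Fit the motion plane of a phase-change field
#'
#' Least-squares fit of the model `dphi/dt = -vx * wx - vy * wy` (no
#' intercept) over the frequency grid, optionally amplitude-weighted.  For a
#' rigidly translating stimulus the phase-change field is dominated by this
#' plane; the fraction of (weighted) variance it explains measures how planar
#' the field is.
#'
#' @param field `M` x `M` matrix of `dphi/dt` values (rad/s) for one block.
#' @param weights optional `M` x `M` nonnegative weights (e.g. the local
#'   amplitude); default unweighted.
#' @param restrict_domain if `TRUE` (default), fit only over the circular
#'   bounded domain `wx^2 + wy^2 < pi^2` used by the Radon stage.
#' @return list with velocity estimates `vx`, `vy` (px/s) and `r2`, the
#'   weighted fraction of variance explained.
#' @export
fit_phase_plane <- function(field, weights = NULL, restrict_domain = TRUE) {
  M <- nrow(field)
  check_even_block(M)
  omega0 <- 2 * pi / M
  s <- signed_index(M) * omega0
  WX <- matrix(s, M, M, byrow = TRUE)  # cols: wx
  WY <- matrix(s, M, M)                # rows: wy
  keep <- if (restrict_domain) (WX^2 + WY^2) < pi^2 else rep(TRUE, M * M)
  f <- field[keep]
  X <- cbind(-WX[keep], -WY[keep])
  w <- if (is.null(weights)) rep(1, length(f)) else weights[keep]
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% f)
  res <- f - X %*% beta
  ss_tot <- sum(w * f^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else NA_real_
  list(vx = beta[1], vy = beta[2], r2 = r2)
}

#' Dump per-block phase fields to a directory of text files
#'
#' Writes the amplitude, phase and (optionally) phase-change arrays of a
#' video's block decomposition as flat CSV files plus a JSON sidecar with the
#' analysis parameters.  (A single hierarchical container would be the
#' natural format, but the package keeps to plain-text outputs.)
#'
#' @param spectra list of `local_spectra` arrays (one per frame).
#' @param dphase optional list from [phase_time_derivative()].
#' @param dir output directory (created if needed).
#' @param params named list of parameters recorded in the sidecar
#'   (e.g. `sigma`, `M`, `b0`, `frame_rate`).
#' @return invisibly, the directory path.
#' @export
dump_phase_fields <- function(spectra, dphase = NULL, dir, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(spectra)) {
    S <- spectra[[t]]
    utils::write.csv(matrix(Mod(S), dim(S)[1] * dim(S)[2]),
                     file.path(dir, sprintf("amplitude_%04d.csv", t)),
                     row.names = FALSE)
    utils::write.csv(matrix(Arg(S) %% (2 * pi), dim(S)[1] * dim(S)[2]),
                     file.path(dir, sprintf("phase_%04d.csv", t)),
                     row.names = FALSE)
  }
  if (!is.null(dphase)) {
    for (t in seq_along(dphase)) {
      D <- dphase[[t]]
      utils::write.csv(matrix(as.numeric(D), dim(D)[1] * dim(D)[2]),
                       file.path(dir, sprintf("dphase_%04d.csv", t)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
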