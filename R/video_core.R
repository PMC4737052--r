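# Frames, video streams, the overlapping block grid, Gaussian windows and
# zero-padded block extraction shared by every downstream stage.

#' Construct a video stream
#'
#' A video stream is an ordered list of frames (real matrices `frame[y, x]`,
#' all of the same size) together with a frame rate in Hz.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param frame_rate frames per second (> 0).
#' @return an object of class `video_stream` with elements `frames`,
#'   `frame_rate`, `Px`, `Py`.
#' @export
video_stream <- function(frames, frame_rate = 50) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("every frame must be a matrix", call. = FALSE)
  }
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("all frames must share the same dimensions", call. = FALSE)
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1)))) {
    stop("frame intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         Px = d[2], Py = d[1]),
    class = "video_stream")
}

#' @method print video_stream
#' @export
print.video_stream <- function(x, ...) {
  cat(sprintf("<video_stream> %d frames of %d x %d pixels @ %g Hz\n",
              length(x$frames), x$Px, x$Py, x$frame_rate))
  invisible(x)
}

#' @export
length.video_stream <- function(x) length(x$frames)

#' Overlapping block grid
#'
#' Tiles a `Px` x `Py` frame with block centers at pixel `(k * b0 + 1,
#' l * b0 + 1)` (1-based), `k = 0, ..., K - 1`, `l = 0, ..., L - 1`, where
#' `K = floor((Px - 1) / b0) + 1` and likewise for `L`.  The block with
#' `k = l = 0` is centered at pixel (1, 1); every center lies inside the
#' frame.
#'
#' @param Px,Py frame width and height in pixels (positive integers).
#' @param b0 spacing between neighboring window centers in pixels.
#' @return an object of class `block_grid` with `K`, `L`, `b0`,
#'   `centers_x` (length `K`), `centers_y` (length `L`), `Px`, `Py`.
#' @examples
#' g <- make_block_grid(156, 112, 6)  # 26 x 19 blocks
#' c(g$K, g$L)
#' @export
make_block_grid <- function(Px, Py, b0) {
  check_positive_int(Px, "Px")
  check_positive_int(Py, "Py")
  check_positive_int(b0, "b0")
  K <- as.integer(floor((Px - 1) / b0) + 1)
  L <- as.integer(floor((Py - 1) / b0) + 1)
  structure(
    list(K = K, L = L, b0 = as.integer(b0),
         centers_x = as.integer((0:(K - 1L)) * b0 + 1),
         centers_y = as.integer((0:(L - 1L)) * b0 + 1),
         Px = as.integer(Px), Py = as.integer(Py)),
    class = "block_grid")
}

#' @method print block_grid
#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d x %d centers, spacing %d px, frame %d x %d\n",
              x$K, x$L, x$b0, x$Px, x$Py))
  invisible(x)
}

#' Gaussian analysis window
#'
#' `M` x `M` sampled Gaussian `exp(-(dx^2 + dy^2) / (2 sigma^2))` whose
#' center (weight exactly 1) sits at patch offset (0, 0), i.e. 0-based patch
#' index `(M/2, M/2)`.  Offsets run over `-M/2, ..., M/2 - 1`, matching the
#' signed frequency indexing of the block FFT, which is why `M` must be even.
#'
#' @param sigma window standard deviation in pixels (> 0).
#' @param M block side in pixels (positive even integer).
#' @return object of class `gaussian_window` with `sigma`, `M`, `weights`
#'   (`M` x `M` matrix, rows are y offsets).
#' @export
make_gaussian_window <- function(sigma, M) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a positive scalar (pixels)", call. = FALSE)
  }
  check_even_block(M)
  d <- signed_index(M)
  W <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))  # rows: dy, cols: dx
  structure(list(sigma = sigma, M = as.integer(M), weights = W),
            class = "gaussian_window")
}

#' Extract a zero-padded block
#'
#' Returns the `M` x `M` neighborhood of `center = c(x, y)` with the center
#' pixel at 0-based patch index `(M/2, M/2)`; positions outside the frame are
#' filled with 0 (boundary blocks are zero-padded rather than dropped).
#'
#' @param frame numeric matrix `frame[y, x]`.
#' @param center integer pixel coordinate `c(x, y)`, 1-based, inside the
#'   frame.
#' @param M block side (positive even integer).
#' @return `M` x `M` numeric matrix (rows are y).
#' @export
extract_block <- function(frame, center, M) {
  if (!is.matrix(frame)) stop("`frame` must be a matrix", call. = FALSE)
  check_even_block(M)
  cx <- center[1]; cy <- center[2]
  Py <- nrow(frame); Px <- ncol(frame)
  if (length(center) != 2L || cx < 1 || cx > Px || cy < 1 || cy > Py) {
    stop("`center` must be a pixel coordinate c(x, y) inside the frame",
         call. = FALSE)
  }
  xs <- (cx - M / 2):(cx + M / 2 - 1)
  ys <- (cy - M / 2):(cy + M / 2 - 1)
  okx <- xs >= 1 & xs <= Px
  oky <- ys >= 1 & ys <= Py
  patch <- matrix(0, M, M)
  patch[oky, okx] <- frame[ys[oky], xs[okx]]
  patch
}
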