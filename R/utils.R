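# Small shared numeric helpers.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the principal interval.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# Index permutation that swaps the two halves of a length-M axis (M even).
# Self-inverse; used both to re-center a patch before the FFT and to reorder
# FFT output into signed-frequency (ascending, DC at M/2 + 1) order.
fftshift_index <- function(M) {
  c((M / 2 + 1):M, 1:(M / 2))
}

# Signed frequency indices m = -M/2, ..., M/2 - 1 (ascending).
signed_index <- function(M) {
  -(M / 2):(M / 2 - 1)
}

#' Frequency grid of an M x M block
#'
#' Radian spatial frequencies `m * omega0`, `omega0 = 2 * pi / M`, for the
#' signed index set `m = -M/2, ..., M/2 - 1` on which block spectra live.
#'
#' @param M block side in pixels (positive even integer).
#' @return list with `M`, `omega0` and the vector `omega` of frequencies
#'   (rad/pixel) in ascending order (DC at position `M/2 + 1`).
#' @export
freq_grid <- function(M) {
  check_even_block(M)
  omega0 <- 2 * pi / M
  list(M = M, omega0 = omega0, omega = signed_index(M) * omega0)
}

check_even_block <- function(M) {
  if (length(M) != 1L || !is.finite(M) || M <= 0 || M != round(M) ||
      M %% 2 != 0) {
    stop("block side `M` must be a positive even integer", call. = FALSE)
  }
  invisible(as.integer(M))
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
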