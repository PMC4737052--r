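# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (double loops) and never call the code paths
# they check.

# Direct double-sum evaluation of the windowed block DFT at signed
# frequency indices, with the spatial origin at the window center.
oracle_block_dft <- function(frame, center, sigma, M) {
  s <- -(M / 2):(M / 2 - 1)
  Py <- nrow(frame); Px <- ncol(frame)
  out <- matrix(0i, M, M)
  for (ni in seq_len(M)) {
    for (mi in seq_len(M)) {
      acc <- 0i
      for (dy in s) {
        for (dx in s) {
          xx <- center[1] + dx
          yy <- center[2] + dy
          u <- if (xx >= 1 && xx <= Px && yy >= 1 && yy <= Py) {
            frame[yy, xx]
          } else 0
          w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
          acc <- acc + u * w *
            exp(-1i * (2 * pi / M) * (s[mi] * dx + s[ni] * dy))
        }
      }
      out[ni, mi] <- acc
    }
  }
  out
}

# Brute-force bounded-domain Radon transform: loops over the grid points of
# the circular domain and accumulates sums/counts per (theta, rho) bin with
# the same nearest-offset rule as the implementation.
oracle_radon <- function(field, n_theta) {
  M <- nrow(field)
  s <- -(M / 2):(M / 2 - 1)
  angles <- (0:(n_theta - 1)) * pi / n_theta
  R <- list()
  cc <- list()
  for (i in seq_len(n_theta)) {
    for (ni in seq_len(M)) {
      for (mi in seq_len(M)) {
        m <- s[mi]; n <- s[ni]
        if (m^2 + n^2 >= (M / 2)^2) next
        rho <- round(m * cos(angles[i]) + n * sin(angles[i]))
        key <- sprintf("%d_%d", i, rho)
        R[[key]] <- (if (is.null(R[[key]])) 0 else R[[key]]) + field[ni, mi]
        cc[[key]] <- (if (is.null(cc[[key]])) 0 else cc[[key]]) + 1
      }
    }
  }
  keys <- names(R)
  parts <- do.call(rbind, strsplit(keys, "_"))
  data.frame(theta_id = as.integer(parts[, 1]),
             rho = as.integer(parts[, 2]),
             R = unlist(R), c = unlist(cc))
}

oracle_pmi <- function(field, n_theta) {
  o <- oracle_radon(field, n_theta)
  max(tapply(abs(o$R / o$c), o$theta_id, sum))
}

# Ideal plane phase-change field -(vx wx + vy wy) on the M x M signed grid.
plane_field <- function(vx, vy, M) {
  omega0 <- 2 * pi / M
  s <- -(M / 2):(M / 2 - 1)
  WX <- matrix(s * omega0, M, M, byrow = TRUE)
  WY <- matrix(s * omega0, M, M)
  -(vx * WX + vy * WY)
}

static_video <- function(value = 0.3, n = 4, Px = 64, Py = 64, fs = 50) {
  video_stream(rep(list(matrix(value, Py, Px)), n), fs)
}

# Signed-grid index of frequency index m (DC at M/2 + 1).
bin_of <- function(m, M) m + M / 2 + 1

# Circular absolute difference of two angles.
ang_diff <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)

# q-ordered flattening of a trig_poly coefficient matrix (ly fastest).
flatten_coefficients <- function(C) as.vector(t(C))
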