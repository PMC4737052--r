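# Phase-only reconstruction: trigonometric-polynomial image space, Gabor
# measurement bank, assembly of the sine-kernel matrix, and the null-space
# solve that recovers the image up to scale from local phases alone.

#' Trigonometric polynomial image space
#'
#' The space of doubly periodic bandlimited images
#' `u(x, y) = sum_{lx, ly} c_{lx, ly} exp(i lx Ox x / Lx) exp(i ly Oy y / Ly)`
#' with orders `Lx`, `Ly` and bandwidths `Ox`, `Oy` (rad/pixel); the periods
#' are `Tx = 2 pi Lx / Ox`, `Ty = 2 pi Ly / Oy` and the dimension is
#' `(2 Lx + 1)(2 Ly + 1)`.  Real images correspond to conjugate-symmetric
#' coefficients `c_{-lx, -ly} = Conj(c_{lx, ly})`.
#'
#' @param Lx,Ly orders (positive integers).
#' @param Omega_x,Omega_y bandwidths in rad/pixel; default `Lx` and `Ly`
#'   (unit periods of `2 pi`).
#' @return object of class `trig_space` with `Lx`, `Ly`, `Ox`, `Oy`, `Tx`,
#'   `Ty`, `dim`.
#' @examples
#' trig_space(63, 63)$dim  # 16129
#' @export
trig_space <- function(Lx, Ly, Omega_x = Lx, Omega_y = Ly) {
  check_positive_int(Lx, "Lx")
  check_positive_int(Ly, "Ly")
  stopifnot(Omega_x > 0, Omega_y > 0)
  Lx <- as.integer(Lx)
  Ly <- as.integer(Ly)
  structure(
    list(Lx = Lx, Ly = Ly,
         Ox = Omega_x, Oy = Omega_y,
         Tx = 2 * pi * Lx / Omega_x, Ty = 2 * pi * Ly / Omega_y,
         dim = (2L * Lx + 1L) * (2L * Ly + 1L)),
    class = "trig_space")
}

#' Trigonometric polynomial
#'
#' @param space a [trig_space()].
#' @param coefficients complex matrix of size `(2Lx+1) x (2Ly+1)`; entry
#'   `[lx + Lx + 1, ly + Ly + 1]` is `c_{lx, ly}`.
#' @return object of class `trig_poly`.
#' @export
trig_poly <- function(space, coefficients) {
  if (!inherits(space, "trig_space")) stop("`space` must be a trig_space")
  if (!is.matrix(coefficients) ||
      nrow(coefficients) != 2 * space$Lx + 1 ||
      ncol(coefficients) != 2 * space$Ly + 1) {
    stop("`coefficients` must be a (2Lx+1) x (2Ly+1) matrix", call. = FALSE)
  }
  structure(list(space = space, coefficients = coefficients),
            class = "trig_poly")
}

# Conjugate flip: C[-lx, -ly] from C[lx, ly].
conj_flip <- function(C) {
  Conj(C[rev(seq_len(nrow(C))), rev(seq_len(ncol(C))), drop = FALSE])
}

#' Random real-valued trigonometric polynomial
#'
#' Draws i.i.d. complex Gaussian coefficients and symmetrizes them
#' (`C <- (Z + conj_flip(Z)) / 2`) so the sampled image is real.
#'
#' @param space a [trig_space()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a [trig_poly()] with conjugate-symmetric coefficients.
#' @export
random_trig_poly <- function(space, seed = 1) {
  nr <- 2 * space$Lx + 1
  nc <- 2 * space$Ly + 1
  Z <- with_seed(seed, {
    matrix(stats::rnorm(nr * nc), nr, nc) +
      1i * matrix(stats::rnorm(nr * nc), nr, nc)
  })
  trig_poly(space, (Z + conj_flip(Z)) / 2)
}

#' Sample a trigonometric polynomial on a uniform grid
#'
#' Evaluates `u` on the `nx` x `ny` uniform grid over `[0, Tx) x [0, Ty)`.
#' The result is exactly periodic with periods `(Tx, Ty)`.
#'
#' @param poly a [trig_poly()].
#' @param nx,ny samples along x and y.
#' @param complex_ok return the complex samples unchecked; otherwise the
#'   imaginary part (which vanishes for conjugate-symmetric coefficients) is
#'   dropped after a sanity check.
#' @return real (or complex) `ny` x `nx` matrix, `u[y, x]`.
#' @export
sample_space <- function(poly, nx = 64, ny = nx, complex_ok = FALSE) {
  sp <- poly$space
  x <- (0:(nx - 1)) * sp$Tx / nx
  y <- (0:(ny - 1)) * sp$Ty / ny
  lx <- -sp$Lx:sp$Lx
  ly <- -sp$Ly:sp$Ly
  Ex <- exp(1i * outer(x, lx) * (sp$Ox / sp$Lx))  # nx x (2Lx+1)
  Ey <- exp(1i * outer(y, ly) * (sp$Oy / sp$Ly))  # ny x (2Ly+1)
  U <- Ey %*% t(poly$coefficients) %*% t(Ex)      # ny x nx
  if (complex_ok) return(U)
  mx <- max(Mod(U))
  if (mx > 0 && max(abs(Im(U))) > 1e-8 * mx) {
    stop("coefficients are not conjugate-symmetric; request complex output",
         call. = FALSE)
  }
  Re(U)
}

#' Gabor measurement bank
#'
#' The receptive-field index set `{(k, l, m, n)}` with translations
#' `0 <= k b0 <= Tx`, `0 <= l b0 <= Ty` and frequencies
#' `-Ox <= m omega0 <= Ox`, `-Oy <= n omega0 <= Oy`, together with the
#' Gaussian window width `sigma`.  Each element defines the complex filter
#' `w(x - k b0, y - l b0) exp(-i (m omega0 (x - k b0) + n omega0 (y - l b0)))`.
#'
#' Quadrature note: all integrals are evaluated over one period with the
#' Gaussian window periodized (wrapped), and `omega0` should be an integer
#' multiple of `2 pi / Tx` so that the periodized integral coincides with the
#' whole-plane one; the uniform-grid rectangle rule is then spectrally
#' accurate.
#'
#' @param space a [trig_space()].
#' @param sigma window standard deviation (same units as `Tx`).
#' @param b0 translation step.
#' @param omega0 frequency step (rad per unit length).
#' @return object of class `gabor_bank`: data frame `fields` with columns
#'   `k`, `l`, `m`, `n` (N rows), plus `sigma`, `b0`, `omega0`, `N`.
#' @export
gabor_bank <- function(space, sigma, b0, omega0) {
  stopifnot(sigma > 0, b0 > 0, omega0 > 0)
  ks <- 0:floor(space$Tx / b0 + 1e-9)
  ls <- 0:floor(space$Ty / b0 + 1e-9)
  ms <- -floor(space$Ox / omega0 + 1e-9):floor(space$Ox / omega0 + 1e-9)
  ns <- -floor(space$Oy / omega0 + 1e-9):floor(space$Oy / omega0 + 1e-9)
  fields <- expand.grid(n = ns, m = ms, l = ls, k = ks,
                        KEEP.OUT.ATTRS = FALSE)[, c("k", "l", "m", "n")]
  structure(list(fields = fields, sigma = sigma, b0 = b0, omega0 = omega0,
                 N = nrow(fields), space = space),
            class = "gabor_bank")
}

# Periodized (wrapped) Gaussian window along one axis.
wrapped_gaussian <- function(x, center, sigma, period, n_wrap = 3) {
  out <- 0
  for (nn in -n_wrap:n_wrap) {
    out <- out + exp(-((x - center + nn * period)^2) / (2 * sigma^2))
  }
  out
}

# Separable complex kernels of the bank along one axis for all (shift, freq)
# combos; columns ordered as combos[i, ] = (shift k, freq m).
axis_kernels <- function(x, shifts, freqs, b0, omega0, sigma, period,
                         conjugate = FALSE) {
  combos <- expand.grid(m = freqs, k = shifts, KEEP.OUT.ATTRS = FALSE)
  sgn <- if (conjugate) 1i else -1i
  G <- matrix(0i, length(x), nrow(combos))
  for (j in seq_len(nrow(combos))) {
    a <- combos$k[j] * b0
    G[, j] <- wrapped_gaussian(x, a, sigma, period) *
      exp(sgn * combos$m[j] * omega0 * (x - a))
  }
  list(G = G, combos = combos)
}

combo_index <- function(combos, k, m) {
  match(paste(k, m), paste(combos$k, combos$m))
}

#' Measure local phases with a Gabor bank
#'
#' Computes the complex response of every receptive field of the bank to the
#' sampled image by the uniform-grid rectangle rule over one period (window
#' periodized; see [gabor_bank()]) and records the phase of each response.
#' Responses whose amplitude falls below `tol` times the maximum amplitude
#' are flagged invalid (phase uninformative at vanishing amplitude).  Only
#' phases and validity flags are stored: reconstruction never sees
#' amplitudes.
#'
#' @param u real `ny` x `nx` matrix sampled by [sample_space()] on the same
#'   grid that will be used for [build_phi()].
#' @param bank a [gabor_bank()].
#' @param space a [trig_space()] (must match the bank's).
#' @param tol relative amplitude threshold for validity (default `1e-10`).
#' @return object of class `phase_measurements`: data frame with columns
#'   `k`, `l`, `m`, `n`, `phi` (in `[0, 2 pi)`) and `valid`.
#' @export
measure_local_phase <- function(u, bank, space = bank$space, tol = 1e-10) {
  ny <- nrow(u); nx <- ncol(u)
  x <- (0:(nx - 1)) * space$Tx / nx
  y <- (0:(ny - 1)) * space$Ty / ny
  f <- bank$fields
  kx <- axis_kernels(x, sort(unique(f$k)), sort(unique(f$m)),
                     bank$b0, bank$omega0, bank$sigma, space$Tx)
  ky <- axis_kernels(y, sort(unique(f$l)), sort(unique(f$n)),
                     bank$b0, bank$omega0, bank$sigma, space$Ty)
  dA <- (space$Tx / nx) * (space$Ty / ny)
  Z <- t(ky$G) %*% u %*% kx$G * dA   # (l,n) combos x (k,m) combos
  ix <- combo_index(kx$combos, f$k, f$m)
  iy <- combo_index(ky$combos, f$l, f$n)
  z <- Z[cbind(iy, ix)]
  A <- Mod(z)
  if (max(A) == 0) {
    valid <- rep(FALSE, length(z))
  } else {
    valid <- A >= tol * max(A)
  }
  meas <- data.frame(k = f$k, l = f$l, m = f$m, n = f$n,
                     phi = Arg(z) %% (2 * pi), valid = valid)
  structure(meas, class = c("phase_measurements", "data.frame"))
}

#' Assemble the sine-kernel matrix
#'
#' Builds the `N_valid x (2Lx+1)(2Ly+1)` complex matrix whose `(p, q)` entry
#' is the quadrature of
#' `w(x - k b0, y - l b0) sin(m w0 (x - k b0) + n w0 (y - l b0) + phi_p)
#' e_{lx, ly}(x, y)` over one period, with columns ordered as
#' `q = (2 Ly + 1)(lx + Lx) + (ly + Ly + 1)`.  Each row states that the image
#' is orthogonal to one phase-shifted real Gabor field, so `Phi c = 0` for
#' the true coefficient vector.  The sine is expanded into two separable
#' complex exponential products, so assembly is a handful of small matrix
#' products.  Invalid measurements are dropped.
#'
#' @param measurements a [measure_local_phase()] result.
#' @param bank the [gabor_bank()] that produced the measurements.
#' @param space the [trig_space()] of the image.
#' @param nx,ny quadrature grid resolution; use the same grid as the
#'   measurements for machine-precision consistency.
#' @return complex matrix of class `phi_matrix` with attributes `space` and
#'   `n_valid`.
#' @export
build_phi <- function(measurements, bank, space = bank$space,
                      nx = 64, ny = nx) {
  f <- measurements[measurements$valid, , drop = FALSE]
  if (nrow(f) == 0L) stop("no valid phase measurements", call. = FALSE)
  x <- (0:(nx - 1)) * space$Tx / nx
  y <- (0:(ny - 1)) * space$Ty / ny
  lx <- -space$Lx:space$Lx
  ly <- -space$Ly:space$Ly
  Ex <- exp(1i * outer(x, lx) * (space$Ox / space$Lx))
  Ey <- exp(1i * outer(y, ly) * (space$Oy / space$Ly))
  dx <- space$Tx / nx
  dy <- space$Ty / ny
  # "+" kernels carry e^{+i m w0 (x - a)}; conjugates give the "-" term
  kxp <- axis_kernels(x, sort(unique(f$k)), sort(unique(f$m)),
                      bank$b0, bank$omega0, bank$sigma, space$Tx,
                      conjugate = TRUE)
  kyp <- axis_kernels(y, sort(unique(f$l)), sort(unique(f$n)),
                      bank$b0, bank$omega0, bank$sigma, space$Ty,
                      conjugate = TRUE)
  A1 <- t(kxp$G) %*% Ex * dx          # (k,m) combos x lx
  B1 <- t(kyp$G) %*% Ey * dy          # (l,n) combos x ly
  A2 <- t(Conj(kxp$G)) %*% Ex * dx
  B2 <- t(Conj(kyp$G)) %*% Ey * dy
  ix <- combo_index(kxp$combos, f$k, f$m)
  iy <- combo_index(kyp$combos, f$l, f$n)
  D <- space$dim
  Phi <- matrix(0i, nrow(f), D)
  for (p in seq_len(nrow(f))) {
    ep <- exp(1i * f$phi[p])
    # outer(lx, ly), flattened with ly fastest to match the q ordering
    term <- (ep * outer(A1[ix[p], ], B1[iy[p], ]) -
               Conj(ep) * outer(A2[ix[p], ], B2[iy[p], ])) / (2i)
    Phi[p, ] <- as.vector(t(term))
  }
  structure(Phi, class = c("phi_matrix", class(Phi)),
            space = space, n_valid = nrow(f))
}

# Real parametrization of conjugate-symmetric coefficient vectors.
# Column q of the coefficient vector is paired with q' = q(-lx, -ly); each
# unordered pair contributes one real and one imaginary degree of freedom,
# and (0, 0) contributes a single real one, for D real parameters in total.
real_param_map <- function(space) {
  Lx <- space$Lx; Ly <- space$Ly
  qs <- function(lx, ly) (2 * Ly + 1) * (lx + Lx) + (ly + Ly + 1)
  self <- qs(0, 0)
  pairs <- list()
  for (lx in -Lx:Lx) {
    for (ly in -Ly:Ly) {
      if (lx > 0 || (lx == 0 && ly > 0)) {
        pairs[[length(pairs) + 1L]] <- c(qs(lx, ly), qs(-lx, -ly))
      }
    }
  }
  list(self = self, pairs = do.call(rbind, pairs), D = space$dim)
}

# Real matrix equivalent of the complex Phi acting on the real parameters.
phi_real <- function(Phi, map) {
  N <- nrow(Phi)
  PR <- matrix(0, N, map$D)
  col <- 1L
  PR[, col] <- Re(Phi[, map$self])
  alpha_self_col <- col
  for (r in seq_len(nrow(map$pairs))) {
    q <- map$pairs[r, 1]
    col <- col + 1L
    PR[, col] <- 2 * Re(Phi[, q])     # alpha: c_q = a + i b, c_q' = a - i b
    col <- col + 1L
    PR[, col] <- -2 * Im(Phi[, q])    # beta
  }
  attr(PR, "alpha_self_col") <- alpha_self_col
  PR
}

params_to_coefficients <- function(d, map, space) {
  cvec <- complex(map$D)
  cvec[map$self] <- d[1]
  col <- 1L
  for (r in seq_len(nrow(map$pairs))) {
    q <- map$pairs[r, 1]; q2 <- map$pairs[r, 2]
    a <- d[col + 1L]; b <- d[col + 2L]
    cvec[q] <- a + 1i * b
    cvec[q2] <- a - 1i * b
    col <- col + 2L
  }
  # q = (2Ly+1)(lx+Lx) + (ly+Ly+1): ly varies fastest, so fill by row
  C <- matrix(cvec, nrow = 2 * space$Ly + 1, ncol = 2 * space$Lx + 1)
  t(C)
}

#' Reconstruct an image from local phases alone
#'
#' Solves `Phi c = 0` for the coefficient vector: without a mean-value row
#' the solution is the right singular vector of the smallest singular value
#' (the reconstruction is determined up to scale); with `add_mean_row` an
#' extra equation fixing the integral of the image makes the augmented
#' least-squares system uniquely solvable.  At least
#' `(2Lx+1)(2Ly+1) - 1` valid measurements are required; if the two smallest
#' singular values are not clearly separated, a warning flags the null-space
#' ambiguity.
#'
#' @param measurements a [measure_local_phase()] result.
#' @param bank the [gabor_bank()] used.
#' @param space the image [trig_space()].
#' @param nx,ny quadrature resolution for [build_phi()] (match the
#'   measurement grid).
#' @param add_mean_row append the mean-value equation.
#' @param mean_value the integral of the image over one period (used with
#'   `add_mean_row`).
#' @param gap_tol relative singular-value threshold below which the second
#'   smallest singular value triggers the ambiguity warning.
#' @return a [trig_poly()], normalized to unit coefficient energy when no
#'   mean row is given; attribute `"singular_values"` carries the spectrum
#'   of the real system.
#' @export
reconstruct_from_phase <- function(measurements, bank, space = bank$space,
                                   nx = 64, ny = nx,
                                   add_mean_row = FALSE, mean_value = 0,
                                   gap_tol = 1e-8) {
  n_valid <- sum(measurements$valid)
  D <- space$dim
  if (n_valid < D - 1) {
    stop(sprintf(paste0(
      "rank deficiency: %d valid phase measurements, but perfect ",
      "reconstruction up to scale requires N >= (2Lx+1)(2Ly+1) - 1 = %d"),
      n_valid, D - 1), call. = FALSE)
  }
  Phi <- build_phi(measurements, bank, space, nx = nx, ny = ny)
  map <- real_param_map(space)
  PR <- phi_real(Phi, map)
  if (add_mean_row) {
    row <- numeric(map$D)
    row[attr(PR, "alpha_self_col")] <- space$Tx * space$Ty
    A <- rbind(PR, row)
    b <- c(numeric(nrow(PR)), mean_value)
    d <- qr.solve(A, b)
    sv <- svd(PR, nu = 0, nv = 0)$d
  } else {
    s <- svd(PR)
    sv <- s$d
    if (sv[D - 1] <= max(gap_tol * sv[1], 10 * sv[D])) {
      warning("null space of Phi is numerically ambiguous (singular gap ",
              "between the two smallest singular values is small)",
              call. = FALSE)
    }
    d <- s$v[, D]
    d <- d / sqrt(sum(d^2))
  }
  C <- params_to_coefficients(d, map, space)
  out <- trig_poly(space, C)
  attr(out, "singular_values") <- sv
  out
}

#' Signal-to-noise ratio of a reconstruction in dB
#'
#' Applies the optimal least-squares scale
#' `lambda* = <u, u_hat> / ||u_hat||^2` to the reconstruction and returns
#' `10 log10(||u||^2 / ||u - lambda* u_hat||^2)`, capped at 300 dB for exact
#' matches.  A reconstruction orthogonal to the original scores 0 dB.
#'
#' @param original,reconstructed real matrices on the same sampling grid.
#' @param cap ceiling in dB.
#' @return SNR in dB.
#' @export
snr_db <- function(original, reconstructed, cap = 300) {
  if (!identical(dim(original), dim(reconstructed))) {
    stop("images must share a sampling grid", call. = FALSE)
  }
  e0 <- sum(original^2)
  if (e0 == 0) stop("`original` must be nonzero", call. = FALSE)
  er <- sum(reconstructed^2)
  lambda <- if (er > 0) sum(original * reconstructed) / er else 0
  err <- sum((original - lambda * reconstructed)^2)
  if (err == 0) return(cap)
  min(cap, 10 * log10(e0 / err))
}
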