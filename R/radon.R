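# Bounded-domain discrete Radon transform with line-length correction, the
# Phase Motion Indicator (PMI), and the direction readout.

#' Circular bounded frequency domain
#'
#' Membership mask of `C = {(wx, wy) in D^2 : wx^2 + wy^2 < pi^2}`, i.e.
#' `m^2 + n^2 < (M/2)^2` in signed index units.
#'
#' @param M block side (positive even integer).
#' @return list with the logical `M` x `M` `mask` (rows: n, cols: m), the
#'   column-major linear indices `idx` of the member bins, and their signed
#'   index coordinates `m`, `n`.
#' @export
bounded_domain <- function(M) {
  check_even_block(M)
  s <- signed_index(M)
  NN <- matrix(s, M, M)                # rows: n  (omega_y)
  MM <- matrix(s, M, M, byrow = TRUE)  # cols: m  (omega_x)
  mask <- (MM^2 + NN^2) < (M / 2)^2
  idx <- which(mask)
  list(mask = mask, idx = idx, m = MM[idx], n = NN[idx], M = as.integer(M))
}

#' Precompute the discrete Radon binning
#'
#' Discretizes the bounded-domain Radon transform by nearest-offset binning:
#' for each of `n_theta` uniform angles `theta in [0, pi)`, every grid point
#' `(m, n)` of the circular domain is assigned to the line with signed offset
#' `rho = round(m cos(theta) + n sin(theta))` (frequency-index units, unit
#' spacing).  The number of points on a line is its discrete length and
#' becomes the correction term `c(rho, theta)`.  The assignment is encoded as
#' a sparse 0/1 matrix so that all blocks of a frame can be transformed with
#' one matrix product.
#'
#' @param M block side (positive even integer).
#' @param n_theta number of angles (>= 2).
#' @return object of class `radon_plan`: sparse matrix `P` (bins x domain
#'   points), per-bin `theta_id`, `theta`, `rho`, lengths `c`, the domain
#'   (`idx`, `m`, `n`), `M`, `n_theta`, and the angle vector `angles`.
#' @export
radon_plan <- function(M, n_theta = 16) {
  dom <- bounded_domain(M)
  if (length(dom$idx) == 0L) stop("empty bounded domain", call. = FALSE)
  if (!is.numeric(n_theta) || length(n_theta) != 1L || n_theta < 2) {
    stop("`n_theta` must be >= 2", call. = FALSE)
  }
  n_theta <- as.integer(n_theta)
  angles <- (0:(n_theta - 1L)) * pi / n_theta
  np <- length(dom$idx)
  rmax <- as.integer(ceiling(M / 2))
  keys <- integer(np * n_theta)
  cols <- integer(np * n_theta)
  for (i in seq_len(n_theta)) {
    rho <- round(dom$m * cos(angles[i]) + dom$n * sin(angles[i]))
    span <- ((i - 1L) * np + 1L):(i * np)
    keys[span] <- (i - 1L) * (2L * rmax + 1L) + (rho + rmax + 1L)
    cols[span] <- seq_len(np)
  }
  fk <- factor(keys)
  bin_of <- as.integer(fk)
  ukeys <- as.integer(levels(fk))
  theta_id <- (ukeys - 1L) %/% (2L * rmax + 1L) + 1L
  rho_u <- (ukeys - 1L) %% (2L * rmax + 1L) - rmax
  P <- Matrix::sparseMatrix(i = bin_of, j = cols, x = 1,
                            dims = c(length(ukeys), np))
  structure(
    list(P = P, theta_id = theta_id, theta = angles[theta_id], rho = rho_u,
         c = Matrix::rowSums(P), idx = dom$idx, m = dom$m, n = dom$n,
         M = dom$M, n_theta = n_theta, angles = angles),
    class = "radon_plan")
}

#' Bounded-domain Radon transform of one block field
#'
#' Sums the field values over each discrete line of the plan;
#' `R(rho, theta)` is the line sum and `c(rho, theta)` the number of
#' contributing grid points (only populated bins are represented).
#'
#' @param field real `M` x `M` matrix (rows: n, cols: m), finite everywhere.
#' @param plan a [radon_plan()] (or `NULL` to build one from `n_theta`).
#' @param n_theta angle count used when `plan` is `NULL`.
#' @return object of class `sinogram`: vectors `R`, `c`, `rho`, `theta`,
#'   `theta_id` over populated bins, plus `angles` and `n_theta`.
#' @export
bounded_radon <- function(field, plan = NULL, n_theta = 16) {
  if (is.null(plan)) plan <- radon_plan(nrow(field), n_theta)
  if (!inherits(plan, "radon_plan")) stop("`plan` must be a radon_plan")
  if (!is.matrix(field) || nrow(field) != plan$M || ncol(field) != plan$M) {
    stop("`field` must be an M x M matrix matching the plan", call. = FALSE)
  }
  if (!all(is.finite(field))) stop("`field` must be finite", call. = FALSE)
  R <- as.numeric(plan$P %*% field[plan$idx])
  structure(
    list(R = R, c = plan$c, rho = plan$rho, theta = plan$theta,
         theta_id = plan$theta_id, angles = plan$angles,
         n_theta = plan$n_theta),
    class = "sinogram")
}

# Per-angle sums of |R / c|; shared by pmi() and motion_direction().
sinogram_angle_sums <- function(sino) {
  v <- rowsum(abs(sino$R / sino$c),
              factor(sino$theta_id, levels = seq_len(sino$n_theta)))
  as.numeric(v)
}

#' Phase Motion Indicator
#'
#' `PMI = max_theta sum_rho | R(rho, theta) / c(rho, theta) |` over the
#' populated bins of the sinogram.  Large for planar (rigid-motion) fields,
#' small for unstructured noise; positively homogeneous of degree 1 in the
#' field.
#'
#' @param sino a [bounded_radon()] sinogram.
#' @return nonnegative scalar.
#' @export
pmi <- function(sino) {
  if (!inherits(sino, "sinogram")) stop("`sino` must be a sinogram")
  if (length(sino$R) == 0L) stop("sinogram has no populated bins", call. = FALSE)
  max(sinogram_angle_sums(sino))
}

#' Direction of motion from a sinogram
#'
#' With `alpha = argmax_theta sum_rho |R / c|`, the direction is
#' `theta_hat = pi * (sign(sum_{rho > 0} R(rho, alpha) / c(rho, alpha)) + 1) / 2
#' + alpha`, reduced mod 2 pi.  In image coordinates +x is rightward and +y
#' downward, so `theta_hat = 0` is rightward motion and `pi / 2` downward.
#'
#' @param sino a [bounded_radon()] sinogram with at least one nonzero value.
#' @return list with `theta_hat` in `[0, 2 pi)`, the argmax angle `alpha`
#'   in `[0, pi)`, and the unit `direction` vector `c(cos, sin)`.
#' @export
motion_direction <- function(sino) {
  if (!inherits(sino, "sinogram")) stop("`sino` must be a sinogram")
  if (all(sino$R == 0)) {
    stop("direction undefined: all Radon values are zero", call. = FALSE)
  }
  sums <- sinogram_angle_sums(sino)
  ai <- which.max(sums)
  alpha <- sino$angles[ai]
  sel <- sino$theta_id == ai & sino$rho > 0
  spos <- sum(sino$R[sel] / sino$c[sel])
  theta_hat <- (pi * (sign(spos) + 1) / 2 + alpha) %% (2 * pi)
  list(theta_hat = theta_hat, alpha = alpha,
       direction = c(cos(theta_hat), sin(theta_hat)))
}

#' PMI of an ideal motion plane
#'
#' The PMI of the noiseless phase-change field
#' `dphi/dt = -(vx wx + vy wy)` on the `M` x `M` grid, used to set
#' detection thresholds in physical units (rad/s).
#'
#' @param vx,vy velocity in px/s.
#' @param plan a [radon_plan()].
#' @return nonnegative scalar PMI.
#' @export
plane_pmi <- function(vx, vy, plan) {
  M <- plan$M
  omega0 <- 2 * pi / M
  s <- signed_index(M) * omega0
  WX <- matrix(s, M, M, byrow = TRUE)
  WY <- matrix(s, M, M)
  pmi(bounded_radon(-(vx * WX + vy * WY), plan))
}
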