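#' Per-voxel permeability field for a labeled block
#'
#' The porous ECM takes the isotropic literature permeability `k_ecm`; SMC
#' voxels are assigned a high flow resistance through a small permeability
#' penalty, so the imaged cells are incorporated directly into the solve
#' without any surface segmentation or meshing.
#'
#' @param block a `voxel_microstructure`.
#' @param k_ecm ECM intrinsic permeability, m^2 (default 1.32e-18, the mean
#'   of fibre-matrix estimates used in the study).
#' @param penalty_factor SMC permeability as a fraction of `k_ecm`; must be
#'   in (0, 1]. The recovered effective permeability is insensitive to the
#'   default over 1e-8 to 1e-4.
#' @return a 3D numeric array of voxel permeabilities, m^2, with the voxel
#'   size (um) attached as `attr(, "voxel_size")`.
#' @export
build_conductance_field <- function(block, k_ecm = 1.32e-18,
                                    penalty_factor = 1e-6) {
  stopifnot(inherits(block, "voxel_microstructure"))
  if (k_ecm <= 0) abort("k_ecm must be > 0")
  if (penalty_factor <= 0 || penalty_factor > 1) {
    abort("penalty_factor must lie in (0, 1]")
  }
  kf <- array(k_ecm, dim(block$labels))
  kf[block$labels == 1L] <- penalty_factor * k_ecm
  attr(kf, "voxel_size") <- block$voxel_size
  kf
}

#' Solve creeping flow through a voxel permeability field
#'
#' Solves the Darcy pressure equation `div((k(x)/mu) grad p) = 0` on a
#' cell-centred finite-volume grid (7-point stencil, harmonic face
#' averaging, so layered media are reproduced exactly). The pressure is
#' fixed on the two faces normal to `axis` (drop `delta_p`); the four
#' lateral faces are no-flux. At the sub-micrometre voxel scale the
#' Brinkman screening length `sqrt(k_ecm)` (about a nanometre) is far below
#' the grid resolution, so the viscous term of the Brinkman equation is
#' negligible and the Darcy limit is used.
#'
#' @param kfield permeability array from [build_conductance_field()], or
#'   any 3D array of voxel permeabilities (m^2) with at least 8 voxels
#'   along the applied axis.
#' @param axis applied-pressure axis, 1 (radial), 2 or 3.
#' @param delta_p pressure drop, Pa (inlet face high).
#' @param voxel_size voxel edge length, um; taken from `kfield`'s
#'   attribute when absent.
#' @param mu dynamic viscosity, Pa s (water at 37 C by default).
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @param max_iter iteration cap.
#' @return a `flow_field`: pressure array (Pa), `mean_velocity` and
#'   `mean_pressure_gradient` 3-vectors (volume averages over the whole
#'   block, m/s and Pa/m), boundary fluxes (m^3/s), mass-balance and
#'   solver residuals.
#' @export
solve_darcy <- function(kfield, axis, delta_p,
                        voxel_size = attr(kfield, "voxel_size"),
                        mu = 6.9e-4, tol = 1e-10, max_iter = 50000L) {
  dims <- dim(kfield)
  stopifnot(length(dims) == 3)
  if (is.null(voxel_size)) abort("voxel_size missing")
  if (delta_p <= 0) abort("delta_p must be > 0")
  if (dims[axis] < 8) abort("need at least 8 voxels along the applied axis")
  h <- rep(voxel_size, length.out = 3) * 1e-6  # um -> m
  p_in <- delta_p
  p_out <- 0
  sol <- .cpp_solve_darcy(as.double(kfield), dims, h, axis - 1L,
                          p_in, p_out, mu, tol, as.integer(max_iter))
  if (!sol$converged) {
    abort(sprintf("Darcy solve did not converge: relres %.3g after %d iterations",
                  sol$relres, sol$iterations))
  }
  p <- sol$pressure
  vol <- prod(dims) * prod(h)

  face_area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  harm <- function(a, b) 2 * a * b / (a + b)
  slice <- function(a, ax, idx) {
    ii <- rep(list(quote(expr = )), 3)
    ii[[ax]] <- idx
    do.call(`[`, c(list(a), ii, list(drop = FALSE)))
  }

  mean_u <- numeric(3)
  mean_g <- numeric(3)
  for (a in 1:3) {
    n <- dims[a]
    klo <- slice(kfield, a, 1:(n - 1))
    khi <- slice(kfield, a, 2:n)
    plo <- slice(p, a, 1:(n - 1))
    phi <- slice(p, a, 2:n)
    kf_face <- harm(klo, khi)
    u_face <- -(kf_face / mu) * (phi - plo) / h[a]  # interior faces
    if (a == axis) {
      # Dirichlet boundary faces (half-cell gradient)
      k1 <- slice(kfield, a, 1)
      kn <- slice(kfield, a, n)
      p1 <- slice(p, a, 1)
      pn <- slice(p, a, n)
      u_in <- -(k1 / mu) * (p1 - p_in) / (h[a] / 2)
      u_outf <- -(kn / mu) * (p_out - pn) / (h[a] / 2)
      # volume average of cell-centred velocities: each cell averages its
      # two faces; equivalently faces weighted (interior 1, boundary 1/2)
      mean_u[a] <- (sum(u_face) + 0.5 * sum(u_in) + 0.5 * sum(u_outf)) /
        prod(dims[-a]) / n
      mean_g[a] <- (p_out - p_in) / (n * h[a])
      flux_in <- sum(u_in) * face_area[a]
      flux_out <- sum(u_outf) * face_area[a]
    } else {
      # lateral no-flux: boundary faces carry zero flux
      mean_u[a] <- sum(u_face) / prod(dims[-a]) / n
      mean_g[a] <- (mean(slice(p, a, n)) - mean(slice(p, a, 1))) /
        ((n - 1) * h[a])
    }
  }

  u_open <- max(kfield) / mu * delta_p / (dims[axis] * h[axis])
  if (abs(mean_u[axis]) < 1e-9 * u_open) {
    warn("near-zero flux: cross-section may be fully blocked")
  }

  structure(
    list(pressure = p, mean_velocity = mean_u,
         mean_pressure_gradient = mean_g,
         flux_in = flux_in, flux_out = flux_out,
         axis = axis, delta_p = delta_p, mu = mu, voxel_size = voxel_size,
         residual_norm = sol$relres, iterations = sol$iterations),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> axis %d, dp = %.4g Pa, <u> = (%.3e, %.3e, %.3e) m/s, relres %.1e (%d it)\n",
    x$axis, x$delta_p, x$mean_velocity[1], x$mean_velocity[2],
    x$mean_velocity[3], x$residual_norm, x$iterations))
  invisible(x)
}

#' Discrete mass-balance residual of a flow field
#'
#' Recomputes every interior divergence from the pressure solution and
#' reports the largest cell imbalance relative to the mean face flux
#' magnitude, plus the global inflow/outflow mismatch.
#'
#' @param field a `flow_field`.
#' @param kfield the permeability array the field was solved on.
#' @return a one-row tibble with `max_divergence_rel` and
#'   `global_balance_rel`.
#' @export
mass_balance <- function(field, kfield) {
  dims <- dim(kfield)
  h <- rep(field$voxel_size, length.out = 3) * 1e-6
  face_area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  p <- field$pressure
  mu <- field$mu
  harm <- function(a, b) 2 * a * b / (a + b)
  div <- array(0, dims)
  scale <- 0
  slice <- function(a, ax, idx) {
    ii <- rep(list(quote(expr = )), 3)
    ii[[ax]] <- idx
    do.call(`[`, c(list(a), ii, list(drop = FALSE)))
  }
  pad <- function(x, ax, side) {
    d <- dim(x); d[ax] <- 1
    z <- array(0, d)
    if (side == "lo") abind_simple(z, x, ax) else abind_simple(x, z, ax)
  }
  for (a in 1:3) {
    n <- dims[a]
    kf_face <- harm(slice(kfield, a, 1:(n - 1)), slice(kfield, a, 2:n))
    q <- -(kf_face / mu) *
      (slice(p, a, 2:n) - slice(p, a, 1:(n - 1))) / h[a] * face_area[a]
    if (a == field$axis) {
      q_in <- -(slice(kfield, a, 1) / mu) *
        (slice(p, a, 1) - field$delta_p) / (h[a] / 2) * face_area[a]
      q_out <- -(slice(kfield, a, n) / mu) *
        (0 - slice(p, a, n)) / (h[a] / 2) * face_area[a]
      qin_full <- abind_simple(q_in, q, a)
      qout_full <- abind_simple(q, q_out, a)
    } else {
      qin_full <- pad(q, a, "lo")
      qout_full <- pad(q, a, "hi")
    }
    div <- div + (qin_full - qout_full)
    scale <- max(scale, max(abs(q)))
  }
  tibble(
    max_divergence_rel = max(abs(div)) / scale,
    global_balance_rel = abs(field$flux_in - field$flux_out) /
      max(abs(field$flux_in), abs(field$flux_out)))
}

# minimal bind of two arrays along one axis
abind_simple <- function(a, b, ax) {
  perm <- c(setdiff(1:3, ax), ax)
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  d <- dim(ap); d[3] <- d[3] + dim(bp)[3]
  out <- array(c(ap, bp), d)
  aperm(out, order(perm))
}
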