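#' Effective permeability tensor by least-squares inversion
#'
#' Darcy's law relates the volume-averaged velocity and pressure gradient
#' of each directional solve through `<u> = -(k/mu) <grad p>`. Three solves
#' with linearly independent mean gradients give nine scalar equations for
#' the six independent components of the symmetric tensor `k`; the
#' over-determined 9 x 6 system is solved by linear least squares, with the
#' symmetry imposed in the parametrization rather than after the fact.
#'
#' @param solutions list of three `flow_field` objects (or any list of
#'   lists carrying `mean_velocity` and `mean_pressure_gradient`).
#' @param mu dynamic viscosity, Pa s.
#' @return a `permeability_tensor`: symmetric 3 x 3 `k` (m^2), principal
#'   values and vectors (see [principal_components()]), the radial
#'   deviation angle and the least-squares residual norm.
#' @export
permeability_tensor_lsq <- function(solutions, mu = 6.9e-4) {
  stopifnot(length(solutions) == 3)
  G <- t(vapply(solutions, function(s) s$mean_pressure_gradient, numeric(3)))
  U <- t(vapply(solutions, function(s) s$mean_velocity, numeric(3)))
  if (qr(G)$rank < 3) abort("mean pressure gradients are rank-deficient")
  # unknowns x = (k11, k22, k33, k12, k13, k23); row for u_i of solve s:
  #   -mu * u_i = sum_j k_ij g_j
  A <- matrix(0, 9, 6)
  b <- numeric(9)
  row <- 0L
  for (s in 1:3) {
    g <- G[s, ]
    rows <- list(
      c(g[1], 0, 0, g[2], g[3], 0),    # k row 1
      c(0, g[2], 0, g[1], 0, g[3]),    # k row 2
      c(0, 0, g[3], 0, g[1], g[2]))    # k row 3
    for (i in 1:3) {
      row <- row + 1L
      A[row, ] <- rows[[i]]
      b[row] <- -mu * U[s, i]
    }
  }
  fit <- lsfit(A, b, intercept = FALSE)
  x <- unname(fit$coefficients)
  k <- matrix(c(x[1], x[4], x[5],
                x[4], x[2], x[6],
                x[5], x[6], x[3]), 3, 3)
  pc <- principal_components(k)
  if (any(pc$principal_values <= 0)) {
    abort(sprintf("recovered tensor is not positive definite (eigenvalues %s)",
                  paste(signif(sort(pc$principal_values), 3), collapse = ", ")))
  }
  structure(
    list(k = k, principal_values = pc$principal_values,
         principal_vectors = pc$principal_vectors,
         radial_deviation_deg = pc$radial_deviation_deg,
         degenerate = pc$degenerate,
         residual_norm = sqrt(sum(fit$residuals^2)) / max(sqrt(sum(b^2)), 1e-300)),
    class = "permeability_tensor")
}

#' @export
print.permeability_tensor <- function(x, ...) {
  pv <- x$principal_values / 1e-18
  cat(sprintf(
    "<permeability_tensor> k_I = %.3g, k_II = %.3g, k_III = %.3g (1e-18 m^2); radial deviation %.2f deg\n",
    pv[1], pv[2], pv[3], x$radial_deviation_deg))
  invisible(x)
}

#' Principal components of a permeability tensor
#'
#' Eigendecomposition of the symmetric tensor. The eigenvector with the
#' largest absolute radial (axis 1) component is labeled k_I -- the
#' approximately radial principal permeability, which in the media is the
#' smallest, so labeling is by alignment and not magnitude. The remaining
#' two are sorted descending as k_II and k_III. The radial deviation is the
#' angle between the k_I eigenvector and the radial axis.
#'
#' @param k symmetric 3 x 3 matrix.
#' @return a list: `principal_values` (k_I, k_II, k_III), orthonormal
#'   `principal_vectors` (columns, matching order), `radial_deviation_deg`
#'   and a `degenerate` flag raised for (near-)repeated eigenvalues, where
#'   the eigenvector basis is arbitrary within the degenerate subspace but
#'   fixed deterministically by the solver.
#' @export
principal_components <- function(k) {
  stopifnot(is.matrix(k), all(dim(k) == 3))
  if (max(abs(k - t(k))) > 1e-8 * max(abs(k))) abort("tensor must be symmetric")
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  degenerate <- min(abs(diff(sort(e$values)))) <
    1e-9 * max(abs(e$values))
  i_rad <- which.max(abs(e$vectors[1, ]))
  rest <- setdiff(1:3, i_rad)
  rest <- rest[order(e$values[rest], decreasing = TRUE)]
  ord <- c(i_rad, rest)
  v <- e$vectors[, ord, drop = FALSE]
  # fix signs so the radial eigenvector points in +radial direction
  v <- sweep(v, 2, sign(v[1, ] + (v[1, ] == 0)), `*`)
  dev <- acos(pmin(1, abs(v[1, 1]))) * 180 / pi
  list(principal_values = e$values[ord], principal_vectors = v,
       radial_deviation_deg = dev, degenerate = degenerate)
}

#' Homogenize a medial block into an effective permeability tensor
#'
#' Orchestrates the full per-block pipeline: builds the voxel permeability
#' field, runs one Darcy solve per coordinate axis, and inverts the three
#' (mean velocity, mean pressure gradient) pairs into the effective tensor.
#'
#' @param block a `voxel_microstructure`.
#' @param k_ecm,penalty_factor see [build_conductance_field()].
#' @param delta_p applied pressure drop per solve, Pa (the problem is
#'   linear in `delta_p`, so its value only sets the scale of the fields).
#' @param mu dynamic viscosity, Pa s.
#' @param tol,max_iter solver controls, see [solve_darcy()].
#' @param keep_fields keep the three `flow_field` objects in the result.
#' @param averaging `"volumetric"` (default) averages velocity over the
#'   whole block including SMC interiors (where it is essentially zero),
#'   the superficial-velocity Darcy convention; `"ecm"` rescales the
#'   tensor by `1/phi_ecm` (Dupuit-Forchheimer) to report the intrinsic
#'   ECM-phase average instead.
#' @return a list with `tensor` (a `permeability_tensor`), `fields`
#'   (list of three `flow_field`s or `NULL`), and `diagnostics` (tibble of
#'   per-axis iterations, residuals and timings).
#' @export
homogenize_block <- function(block, k_ecm = 1.32e-18, penalty_factor = 1e-6,
                             delta_p = 100, mu = 6.9e-4, tol = 1e-10,
                             max_iter = 50000L, keep_fields = FALSE,
                             averaging = c("volumetric", "ecm")) {
  averaging <- match.arg(averaging)
  kf <- build_conductance_field(block, k_ecm, penalty_factor)
  fields <- vector("list", 3)
  diag_rows <- vector("list", 3)
  for (a in 1:3) {
    t0 <- proc.time()[["elapsed"]]
    fields[[a]] <- solve_darcy(kf, axis = a, delta_p = delta_p,
                               mu = mu, tol = tol, max_iter = max_iter)
    diag_rows[[a]] <- tibble(
      axis = a, iterations = fields[[a]]$iterations,
      residual = fields[[a]]$residual_norm,
      seconds = proc.time()[["elapsed"]] - t0)
  }
  tensor <- permeability_tensor_lsq(fields, mu = mu)
  if (averaging == "ecm") {
    phi_ecm <- mean(block$labels == 0L)
    tensor$k <- tensor$k / phi_ecm
    tensor$principal_values <- tensor$principal_values / phi_ecm
  }
  list(tensor = tensor,
       fields = if (keep_fields) fields else NULL,
       diagnostics = dplyr::bind_rows(diag_rows))
}

#' Tidy a permeability tensor
#'
#' @param x a `permeability_tensor`.
#' @param ... unused.
#' @return a tibble with one row per principal component: value (m^2),
#'   value in 1e-18 m^2, and the radial deviation of the k_I axis.
#' @export
tidy.permeability_tensor <- function(x, ...) {
  tibble(component = c("k_I", "k_II", "k_III"),
         permeability_m2 = x$principal_values,
         permeability_1e18_m2 = x$principal_values / 1e-18,
         radial_deviation_deg = c(x$radial_deviation_deg, NA, NA))
}
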