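#' Hydraulic conductance from a bubble-displacement trace
#'
#' The bubble's steady displacement rate in the graduated capillary gives
#' the volumetric flow across the wall:
#' `L_p = (dx/dt) * (pi D^2 / 4) / (A * delta_p)`, with the slope `dx/dt`
#' estimated by least squares over the whole trace. The whole-wall
#' hydraulic resistance is `R_WALL = 1 / L_p`.
#'
#' @param trace a `bubble_trace` (see [generate_bubble_trace()]), or any
#'   data frame with `time` and `displacement` plus `capillary_diameter`,
#'   `surface_area` and `delta_p` attributes (SI units).
#' @return a one-row tibble: `slope` (m/s), `lp` (m s^-1 Pa^-1),
#'   `lp_cm_s_mmHg` (cm s^-1 mmHg^-1, the common literature unit),
#'   `r_wall` (Pa s/m; `Inf` with a warning for a stalled bubble).
#' @export
lp_from_trace <- function(trace) {
  stopifnot(all(c("time", "displacement") %in% names(trace)))
  D <- attr(trace, "capillary_diameter")
  A <- attr(trace, "surface_area")
  dp <- attr(trace, "delta_p")
  if (is.null(D) || is.null(A) || is.null(dp) || D <= 0 || A <= 0 || dp <= 0) {
    abort("trace must carry positive capillary_diameter, surface_area, delta_p")
  }
  if (nrow(trace) < 3) abort("need at least 3 samples")
  slope <- unname(coef(lm(displacement ~ time, data = trace))[2])
  if (slope < 0) abort("negative slope: bubble moving backwards")
  lp <- slope * (pi * D^2 / 4) / (A * dp)
  if (lp == 0) warn("zero slope: infinite wall resistance")
  tibble(slope = slope, lp = lp,
         lp_cm_s_mmHg = lp * 100 * PA_PER_MMHG,
         r_wall = ifelse(lp > 0, 1 / lp, Inf))
}

#' Area-weighted mean medial thickness
#'
#' The conductance measurement spans the whole aorto-iliac bifurcation, so
#' the medial thickness entering the resistance decomposition is the mean
#' of the segment thicknesses weighted by their shares of the total
#' surface area.
#'
#' @param thicknesses segment medial thicknesses (um or m; the result is
#'   in the same unit).
#' @param area_fractions matching surface-area fractions; must sum to 1
#'   within 0.02.
#' @return the weighted mean thickness.
#' @export
weighted_medial_thickness <- function(thicknesses, area_fractions) {
  stopifnot(length(thicknesses) == length(area_fractions))
  if (abs(sum(area_fractions) - 1) > 0.02) {
    abort("area fractions must sum to 1 (within 0.02)")
  }
  sum(thicknesses * area_fractions) / sum(area_fractions)
}

#' Medial hydraulic resistance from radial permeability
#'
#' A Darcy slab of thickness `T` and radial permeability `k` resists water
#' flow with `R_MED = mu * T / k` (Pa s/m).
#'
#' @param k_radial radial effective permeability, m^2.
#' @param thickness medial thickness, m.
#' @param mu dynamic viscosity of water, Pa s (37 C default).
#' @return medial resistance, Pa s/m (vectorized over `k_radial`).
#' @export
medial_resistance <- function(k_radial, thickness, mu = 6.9e-4) {
  if (any(k_radial <= 0) || thickness <= 0 || mu <= 0) {
    abort("k_radial, thickness and mu must be positive")
  }
  mu * thickness / k_radial
}

#' Intimal resistance by subtraction
#'
#' Intima and media act in series, so `R_INT = R_WALL - R_MED`. A negative
#' result (the medial estimate exceeding the measured wall) is physically
#' inconsistent; it is returned as-is with `inconsistent = TRUE` rather
#' than raised as an error, since the subtraction itself is the method.
#'
#' @param r_wall whole-wall resistance(s), Pa s/m.
#' @param r_med medial resistance(s), Pa s/m.
#' @return a tibble with `r_int` and an `inconsistent` flag.
#' @export
intimal_resistance <- function(r_wall, r_med) {
  if (any(r_wall <= 0)) abort("r_wall must be positive")
  r_int <- r_wall - r_med
  tibble(r_int = r_int, inconsistent = r_int < 0)
}

#' Crossover pressure of medial and intimal resistances
#'
#' Finds the pressure(s) where `R_MED(p) = R_INT(p)` by scanning a fine
#' grid for sign changes of the difference and polishing each bracket by
#' bisection (`uniroot`). Fitted curves, not raw points, should be
#' supplied.
#'
#' @param r_med_fn,r_int_fn functions of pressure (mmHg) returning
#'   resistances.
#' @param interval pressure interval to search, mmHg.
#' @param n_grid scan resolution.
#' @return a tibble of roots (`crossover_mmHg`), zero rows when the curves
#'   do not cross; a `multiple` flag marks more than one root, and a
#'   warning is raised for tangency (a sign-degenerate touch).
#' @export
crossover_pressure <- function(r_med_fn, r_int_fn, interval = c(40, 120),
                               n_grid = 2000L) {
  pg <- seq(interval[1], interval[2], length.out = n_grid)
  d <- r_med_fn(pg) - r_int_fn(pg)
  sgn <- sign(d)
  roots <- numeric(0)
  touched <- any(sgn == 0)
  for (i in seq_len(n_grid - 1)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      r <- uniroot(function(p) r_med_fn(p) - r_int_fn(p),
                   c(pg[i], pg[i + 1]), tol = 1e-6)
      roots <- c(roots, r$root)
    } else if (sgn[i + 1] == 0) {
      roots <- c(roots, pg[i + 1])
    }
  }
  roots <- unique(round(roots, 6))
  if (touched) warn("tangency: curves touch without crossing at some root")
  if (length(roots) > 1) warn("multiple crossover pressures found")
  tibble(crossover_mmHg = roots,
         multiple = rep(length(roots) > 1, length(roots)))
}

#' Decompose whole-wall resistance into intimal and medial parts
#'
#' The headline analysis: sigmoid fits of whole-wall conductance L_p(p)
#' and radial medial permeability k(p) against transmural pressure are
#' combined into resistance profiles `R_WALL = 1/L_p`,
#' `R_MED = mu T / k`, `R_INT = R_WALL - R_MED` on a pressure grid,
#' together with uncertainty bands from scaling the assumed ECM
#' permeability by +/- `kecm_band` (the medial permeability is linear in
#' the ECM permeability, so rescaling replaces a re-solve), and the
#' crossover pressure where the medial resistance overtakes the intimal
#' one.
#'
#' @param lp_data data frame with `pressure` (mmHg) and `lp`
#'   (m s^-1 Pa^-1).
#' @param k_data data frame with `pressure` (mmHg) and `k` (m^2, radial
#'   component).
#' @param thickness_um area-weighted medial thickness, um.
#' @param mu dynamic viscosity, Pa s.
#' @param kecm_band relative half-width of the ECM-permeability band
#'   (0.20 for the +/-20 percent literature spread; 0 collapses the
#'   bands).
#' @param pressure_grid evaluation grid, mmHg.
#' @param seed passed to the sigmoid fits.
#' @return a `resistance_profile`: a tibble (pressure, r_wall, r_med,
#'   r_int, r_med_lo/hi, r_int_lo/hi, inconsistent) with the crossover
#'   table, band factor and the two sigmoid fits as attributes.
#' @export
resistance_profile <- function(lp_data, k_data, thickness_um = 36.7,
                               mu = 6.9e-4, kecm_band = 0.20,
                               pressure_grid = seq(40, 120, by = 0.5),
                               seed = 1L) {
  stopifnot(all(c("pressure", "lp") %in% names(lp_data)),
            all(c("pressure", "k") %in% names(k_data)))
  fit_lp <- fit_sigmoid(lp_data, pressure, lp, seed = seed)
  fit_k <- fit_sigmoid(k_data, pressure, k, seed = seed)
  thickness <- thickness_um * 1e-6
  r_wall_fn <- function(p) 1 / fit_lp$fn(p)
  r_med_fn <- function(p) medial_resistance(fit_k$fn(p), thickness, mu)
  r_int_fn <- function(p) r_wall_fn(p) - r_med_fn(p)
  r_wall <- r_wall_fn(pressure_grid)
  r_med <- r_med_fn(pressure_grid)
  ri <- intimal_resistance(r_wall, r_med)
  # k scales linearly with k_ECM, so the band is a reciprocal rescale
  r_med_lo <- r_med / (1 + kecm_band)
  r_med_hi <- r_med / (1 - kecm_band)
  cross <- crossover_pressure(r_med_fn, r_int_fn,
                              interval = range(pressure_grid))
  out <- tibble(pressure = pressure_grid, r_wall = r_wall, r_med = r_med,
                r_int = ri$r_int,
                r_med_lo = r_med_lo, r_med_hi = r_med_hi,
                r_int_lo = r_wall - r_med_hi, r_int_hi = r_wall - r_med_lo,
                inconsistent = ri$inconsistent)
  class(out) <- c("resistance_profile", class(out))
  attr(out, "crossover") <- cross
  attr(out, "kecm_band") <- kecm_band
  attr(out, "fit_lp") <- fit_lp
  attr(out, "fit_k") <- fit_k
  attr(out, "thickness_um") <- thickness_um
  attr(out, "mu") <- mu
  out
}

#' Rescale the ECM-permeability uncertainty band of a profile
#'
#' Recomputes the `r_med`/`r_int` bands of an existing profile for a
#' different band factor, exploiting the linearity of the homogenized
#' permeability in the ECM permeability (no re-solve needed).
#'
#' @param profile a `resistance_profile`.
#' @param factor new relative half-width (0 collapses the bands onto the
#'   central estimate).
#' @return the profile with updated band columns.
#' @export
kecm_uncertainty_band <- function(profile, factor = 0.20) {
  stopifnot(inherits(profile, "resistance_profile"))
  if (factor < 0 || factor >= 1) abort("factor must lie in [0, 1)")
  profile$r_med_lo <- profile$r_med / (1 + factor)
  profile$r_med_hi <- profile$r_med / (1 - factor)
  profile$r_int_lo <- profile$r_wall - profile$r_med_hi
  profile$r_int_hi <- profile$r_wall - profile$r_med_lo
  attr(profile, "kecm_band") <- factor
  profile
}

#' @export
print.resistance_profile <- function(x, ...) {
  cross <- attr(x, "crossover")
  cat(sprintf(
    "<resistance_profile> %d pressures in [%.0f, %.0f] mmHg, band +/-%.0f%%, crossover %s mmHg\n",
    nrow(x), min(x$pressure), max(x$pressure), 100 * attr(x, "kecm_band"),
    if (nrow(cross) == 0) "absent" else
      paste(signif(cross$crossover_mmHg, 4), collapse = ", ")))
  NextMethod()
}

#' @rdname resistance_profile
#' @param x a `resistance_profile`.
#' @param ... unused.
#' @export
glance.resistance_profile <- function(x, ...) {
  cross <- attr(x, "crossover")
  tibble(crossover_mmHg = if (nrow(cross)) cross$crossover_mmHg[1] else NA_real_,
         n_crossovers = nrow(cross),
         kecm_band = attr(x, "kecm_band"),
         thickness_um = attr(x, "thickness_um"),
         any_inconsistent = any(x$inconsistent))
}
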