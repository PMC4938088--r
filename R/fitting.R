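#' Parameters of the deformation-dependent permeability law
#'
#' The radial permeability of the media as a function of the volumetric
#' ratio `J` factors into three parts: the reference-state permeability
#' `k0` (the value at 0 mmHg, where `J = 1`); a conservation constraint
#' `((J - phi_s_ref) / (1 - phi_s_ref))^m` with `m = 0.2`, which closes
#' the permeability when the water-bearing pores are fully shut
#' (`J -> phi_s_ref`, far beyond physiological pressures); and a fitted
#' physical term describing the pressure-driven microstructural
#' rearrangement (see [constitutive_phys()]).
#'
#' @param k0 reference-state permeability, in the working permeability
#'   scale (default scale 1e-18 m^2, so the fitted aortic value is 5.51).
#' @param p1 weight of the gradual pore-space mode, in (0, 1).
#' @param p2 power-law exponent of the gradual mode.
#' @param p3 elbow location: the J at which the steep mode is half-way
#'   down.
#' @param p4 decay (steepness) of the steep mode.
#' @param m conservation-constraint exponent (0.2).
#' @param phi_s_ref reference solid fraction phi0^S; not printed in the
#'   source data and therefore configured (0.60 by default, consistent
#'   with a reference SMC fraction near 0.2 and ECM mobile-water fraction
#'   near 0.5).
#' @return an object of class `constitutive_params`.
#' @export
constitutive_params <- function(k0 = 5.51, p1 = 0.52, p2 = 0.52,
                                p3 = 0.95, p4 = 55.12,
                                m = 0.2, phi_s_ref = 0.6) {
  if (k0 <= 0) abort("k0 must be > 0")
  if (m <= 0) abort("m must be > 0")
  if (phi_s_ref <= 0 || phi_s_ref >= 1) abort("phi_s_ref must lie in (0, 1)")
  if (p1 <= 0 || p1 >= 1) abort("p1 must lie in (0, 1)")
  if (p2 <= 0 || p4 <= 0) abort("p2 and p4 must be > 0")
  structure(list(k0 = k0, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 m = m, phi_s_ref = phi_s_ref),
            class = "constitutive_params")
}

#' Physical term of the permeability law
#'
#' Two-mode description of how medial microstructure controls radial
#' permeability as the tissue compacts, isolated in this one function so
#' the functional form is auditable and replaceable in a single place:
#'
#' `f_phys(J) = p1 * C(J)^p2 + (1 - p1) * sigma(J) / sigma(1)`
#'
#' where `C(J) = (J - phi_s_ref) / (1 - phi_s_ref)` is the normalized pore
#' fraction and `sigma(J) = 1 / (1 + exp(-p4 (J - p3)))`. The logistic
#' mode is the steep loss of permeability as intercellular channels narrow
#' (the "elbow" near `J = p3`); the power-law mode is the gradual decline
#' from shrinking pore space. By construction `f_phys(1) = 1`, so the law
#' evaluates to `k0` exactly in the reference state.
#'
#' @param J volumetric ratio(s), each in (`phi_s_ref`, 1].
#' @param p1,p2,p3,p4 law parameters, see [constitutive_params()].
#' @param phi_s_ref reference solid fraction.
#' @return the dimensionless physical factor.
#' @export
constitutive_phys <- function(J, p1, p2, p3, p4, phi_s_ref) {
  C <- (J - phi_s_ref) / (1 - phi_s_ref)
  sig <- 1 / (1 + exp(-p4 * (J - p3)))
  sig1 <- 1 / (1 + exp(-p4 * (1 - p3)))
  p1 * C^p2 + (1 - p1) * sig / sig1
}

#' Evaluate the deformation-dependent permeability law
#'
#' `k(J) = k0 * ((J - phi_s_ref)/(1 - phi_s_ref))^m * f_phys(J)`.
#'
#' @param J volumetric ratio(s); every value must exceed `phi_s_ref`
#'   (beyond that bound the pores are closed and no transmural flow
#'   occurs).
#' @param params a [constitutive_params()] object.
#' @return permeability in the same scale units as `k0`.
#' @export
constitutive_eval <- function(J, params) {
  stopifnot(inherits(params, "constitutive_params"))
  if (any(J <= params$phi_s_ref)) {
    abort("J must exceed phi_s_ref: pores closed, no transmural flow")
  }
  C <- (J - params$phi_s_ref) / (1 - params$phi_s_ref)
  params$k0 * C^params$m *
    constitutive_phys(J, params$p1, params$p2, params$p3, params$p4,
                      params$phi_s_ref)
}

# Latin-hypercube multi-start points within bounds (first row is the
# data-driven heuristic start)
constitutive_starts <- function(J, k, m, phi_s_ref, n_starts, lower, upper) {
  C <- ((J - phi_s_ref) / (1 - phi_s_ref))^m
  kc <- k / C
  k0h <- kc[which.max(J)]
  plateau <- median(kc[J <= quantile(J, 0.3)]) / k0h
  p1h <- min(max(plateau, 0.05), 0.95)
  fr <- kc / k0h
  p3h <- J[which.min(abs(fr - (p1h + 1) / 2))]
  heur <- c(k0h, p1h, 0.5, min(max(p3h, lower[4]), upper[4]), 40)
  u <- lhs::randomLHS(n_starts - 1L, 5L)
  lhs_pts <- t(apply(u, 1, function(z) lower + z * (upper - lower)))
  rbind(heur, lhs_pts)
}

#' Fit the permeability constitutive law
#'
#' Fits `(k0, p1, p2, p3, p4)` to `(J, k)` data by bounded
#' Levenberg-Marquardt least squares on log-permeability residuals (the
#' homogenized permeabilities carry multiplicative scatter, so the log
#' scale is the natural residual scale), with a seeded Latin-hypercube
#' multi-start plus one data-driven heuristic start. The conservation
#' exponent `m` and the reference solid fraction are held fixed, and the
#' fit is meaningful only over the J range of the data.
#'
#' @param data a data frame with columns `J` and `k`, at least 8 points.
#' @param m_fixed conservation exponent (held at 0.2).
#' @param phi_s_ref_fixed reference solid fraction (held fixed).
#' @param n_starts number of optimizer starts (>= 1; the first is always
#'   the heuristic start).
#' @param seed seed for the Latin-hypercube starts.
#' @return a `constitutive_fit`: the fitted [constitutive_params()], RSS
#'   (on log residuals), parameter standard errors from the Jacobian, the
#'   start that won, and convergence info. Poorly identified fits (any
#'   relative standard error above 25 percent) raise a warning carrying
#'   the parameter covariance.
#' @export
fit_constitutive <- function(data, m_fixed = 0.2, phi_s_ref_fixed = 0.6,
                             n_starts = 20L, seed = 1L) {
  stopifnot(all(c("J", "k") %in% names(data)))
  J <- data$J
  k <- data$k
  if (length(J) < 8) abort("need at least 8 (J, k) points")
  if (any(J <= phi_s_ref_fixed)) abort("all J must exceed phi_s_ref_fixed")
  if (any(k <= 0)) abort("permeabilities must be positive")
  lower <- c(1e-6, 1e-3, 1e-3, phi_s_ref_fixed + 0.02, 1)
  upper <- c(max(k) * 100, 0.999, 20, 0.999, 500)
  logk <- log(k)
  resid_fn <- function(par) {
    pars <- list(k0 = par[1], p1 = par[2], p2 = par[3], p3 = par[4],
                 p4 = par[5], m = m_fixed, phi_s_ref = phi_s_ref_fixed)
    C <- (J - phi_s_ref_fixed) / (1 - phi_s_ref_fixed)
    log(par[1] * C^m_fixed *
          constitutive_phys(J, par[2], par[3], par[4], par[5],
                            phi_s_ref_fixed)) - logk
  }
  set.seed(seed)
  starts <- constitutive_starts(J, k, m_fixed, phi_s_ref_fixed,
                                n_starts, lower, upper)
  best <- NULL
  best_start <- NA_integer_
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) {
      best <- f
      best_start <- i
    }
  }
  if (is.null(best)) abort("no optimizer start converged")
  par <- best$par
  params <- constitutive_params(k0 = par[1], p1 = par[2], p2 = par[3],
                                p3 = par[4], p4 = par[5],
                                m = m_fixed, phi_s_ref = phi_s_ref_fixed)
  # identifiability diagnostics from the Jacobian at the optimum
  n <- length(J)
  sigma2 <- best$deviance / max(n - 5, 1)
  Jm <- vapply(1:5, function(i) {
    hstep <- pmax(abs(par[i]), 1e-4) * 1e-6
    pp <- par; pm <- par
    pp[i] <- pp[i] + hstep; pm[i] <- pm[i] - hstep
    (resid_fn(pp) - resid_fn(pm)) / (2 * hstep)
  }, numeric(n))
  cov <- tryCatch(solve(crossprod(Jm)) * sigma2, error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, 5) else sqrt(pmax(diag(cov), 0))
  rel_se <- se / abs(par)
  if (is.null(cov) || any(!is.finite(rel_se)) || any(rel_se > 0.25)) {
    warn(paste0("constitutive fit poorly identified; relative standard ",
                "errors: ", paste(signif(rel_se, 2), collapse = ", ")))
  }
  structure(
    list(params = params, rss = best$deviance, n = n,
         std_errors = setNames(se, c("k0", "p1", "p2", "p3", "p4")),
         covariance = cov, winning_start = best_start, seed = seed,
         n_starts = n_starts, data = tibble(J = J, k = k)),
    class = "constitutive_fit")
}

#' @export
print.constitutive_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<constitutive_fit> k0 = %.3f, p1 = %.3f, p2 = %.3f, p3 = %.3f, p4 = %.2f (m = %.2g, phi0^S = %.2f fixed), log-RSS = %.3g\n",
    p$k0, p$p1, p$p2, p$p3, p$p4, p$m, p$phi_s_ref, x$rss))
  invisible(x)
}

#' @rdname fit_constitutive
#' @param x a `constitutive_fit`.
#' @param ... unused.
#' @export
tidy.constitutive_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("k0", "p1", "p2", "p3", "p4"),
         estimate = c(p$k0, p$p1, p$p2, p$p3, p$p4),
         std.error = unname(x$std_errors))
}

#' @rdname fit_constitutive
#' @export
glance.constitutive_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n, n_starts = x$n_starts,
         winning_start = x$winning_start,
         m = x$params$m, phi_s_ref = x$params$phi_s_ref)
}

#' Fit a four-parameter logistic (sigmoid)
#'
#' `y = lower + (upper - lower) / (1 + exp((midpoint - x) / scale))`,
#' fitted by Levenberg-Marquardt least squares with a data-driven start
#' plus seeded random restarts. Used for conductance-pressure,
#' permeability-pressure and solid-fraction-pressure relations.
#'
#' @param data a data frame; needs at least 5 points.
#' @param x,y column names (tidy-eval) of predictor and response.
#' @param n_starts optimizer starts.
#' @param seed seed for the random restarts.
#' @param scale_sign constrain the slope direction: `0` free (default),
#'   `+1` increasing, `-1` decreasing.
#' @return a `sigmoid_fit` with `tidy()`/`glance()` methods and a
#'   `predict()` method. A degenerate fit (`upper` and `lower` within 1
#'   percent of the data range) is flagged with a warning and
#'   `degenerate = TRUE`.
#' @export
fit_sigmoid <- function(data, x = "x", y = "y", n_starts = 10L, seed = 1L,
                        scale_sign = 0) {
  xv <- rlang::eval_tidy(rlang::ensym(x), data)
  yv_raw <- rlang::eval_tidy(rlang::ensym(y), data)
  if (length(xv) < 5) abort("need at least 5 points")
  # work on an O(1) response scale (conductances and permeabilities live
  # at 1e-12 .. 1e-19); plateaus are rescaled on the way out
  yscale <- max(abs(yv_raw), 1e-300)
  yv <- yv_raw / yscale
  rngx <- diff(range(xv))
  rngy <- diff(range(yv))
  model <- function(par, xx) {
    par[1] + (par[2] - par[1]) / (1 + exp((par[3] - xx) / par[4]))
  }
  resid_fn <- function(par) model(par, xv) - yv
  set.seed(seed)
  lo_y <- min(yv) - rngy
  hi_y <- max(yv) + rngy
  s_lo <- if (scale_sign > 0) 1e-3 * rngx else -10 * rngx
  s_hi <- if (scale_sign < 0) -1e-3 * rngx else 10 * rngx
  lower <- c(lo_y, lo_y, min(xv) - rngx, s_lo)
  upper <- c(hi_y, hi_y, max(xv) + rngx, s_hi)
  starts <- rbind(
    c(min(yv), max(yv), median(xv), 0.25 * rngx * ifelse(scale_sign < 0, -1, 1)),
    cbind(runif(n_starts - 1, lo_y, hi_y), runif(n_starts - 1, lo_y, hi_y),
          runif(n_starts - 1, min(xv), max(xv)),
          runif(n_starts - 1,
                ifelse(scale_sign > 0, 0.02, -2) * rngx,
                ifelse(scale_sign < 0, -0.02, 2) * rngx)))
  starts[, 4][starts[, 4] == 0] <- 0.1 * rngx
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
  }
  if (is.null(best)) abort("sigmoid fit failed from every start")
  par <- setNames(best$par, c("lower", "upper", "midpoint", "scale"))
  if (par[["scale"]] < 0) {
    # the 4PL has a mirror parametrization (swap plateaus, negate scale)
    # describing the same curve; canonicalize to positive scale
    par[c("lower", "upper")] <- par[c("upper", "lower")]
    par[["scale"]] <- -par[["scale"]]
  }
  degenerate <- abs(par["upper"] - par["lower"]) < 0.01 * max(rngy, 1e-12)
  if (degenerate) warn("degenerate sigmoid: upper and lower plateaus coincide")
  par[c("lower", "upper")] <- par[c("lower", "upper")] * yscale
  structure(
    list(params = par, rss = best$deviance * yscale^2, n = length(xv),
         n_params = 4L, degenerate = degenerate,
         data = tibble(x = xv, y = yv_raw),
         fn = function(xx) par[["lower"]] +
           (par[["upper"]] - par[["lower"]]) /
           (1 + exp((par[["midpoint"]] - xx) / par[["scale"]]))),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> lower = %.4g, upper = %.4g, midpoint = %.4g, scale = %.4g (n = %d, rss = %.4g)\n",
    x$params[1], x$params[2], x$params[3], x$params[4], x$n, x$rss))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  object$fn(xx)
}

#' @rdname fit_sigmoid
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_sigmoid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n, n_params = x$n_params,
         aicc = aicc(x$rss, x$n, x$n_params), degenerate = x$degenerate)
}

#' Corrected Akaike information criterion
#'
#' `AICc = n log(rss / n) + 2K + 2K(K + 1) / (n - K - 1)`, the
#' least-squares form with the small-sample correction; requires
#' `n > K + 1`.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param n_params number of fitted parameters K.
#' @return the AICc value.
#' @export
aicc <- function(rss, n, n_params) {
  if (any(n <= n_params + 1)) abort("AICc needs n > n_params + 1")
  n * log(rss / n) + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n - n_params - 1)
}

#' Rank competing fits of one dataset by AICc
#'
#' @param fits either a data frame with columns `model`, `rss`, `n`,
#'   `n_params`, or a named list of fit objects answering `glance()` with
#'   `rss`, `nobs`, `n_params` (e.g. `sigmoid_fit` or [polynomial_fit()]
#'   results). All fits must be to the same data (`n` equal).
#' @return the tibble sorted by ascending AICc (first row preferred), with
#'   a `delta_aicc` column.
#' @export
aicc_compare <- function(fits) {
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    dplyr::bind_rows(purrr::imap(fits, function(f, nm) {
      g <- glance(f)
      tibble(model = nm, rss = g$rss, n = g$nobs, n_params = g$n_params)
    }))
  }
  stopifnot(all(c("model", "rss", "n", "n_params") %in% names(tab)))
  if (length(unique(tab$n)) != 1) {
    abort("all fits must be computed on the same data (equal n)")
  }
  tab <- dplyr::mutate(tab,
                       aicc = aicc(.data$rss, .data$n, .data$n_params))
  tab <- dplyr::arrange(tab, .data$aicc)
  dplyr::mutate(tab, delta_aicc = .data$aicc - .data$aicc[1])
}

#' Polynomial least-squares fit (comparison model)
#'
#' Degree-d polynomial fitted by ordinary least squares; a comparison
#' model for AICc ranking against the sigmoid.
#'
#' @param data a data frame.
#' @param x,y column names (tidy-eval).
#' @param degree polynomial degree (1 = linear).
#' @return an object with `rss`, `nobs`, `n_params` compatible with
#'   [aicc_compare()].
#' @export
polynomial_fit <- function(data, x = "x", y = "y", degree = 1L) {
  xv <- rlang::eval_tidy(rlang::ensym(x), data)
  yv <- rlang::eval_tidy(rlang::ensym(y), data)
  fit <- lm(yv ~ stats::poly(xv, degree))
  structure(list(rss = sum(fit$residuals^2), n = length(xv),
                 n_params = degree + 1L, lm = fit),
            class = "polynomial_fit")
}

#' @export
glance.polynomial_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n, n_params = x$n_params,
         aicc = aicc(x$rss, x$n, x$n_params))
}
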