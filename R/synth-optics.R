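#' Optical parameters for synthetic confocal stacks
#'
#' @param attenuation_length exponential decay length of fluorescence
#'   intensity with imaging depth, um.
#' @param noise_sd Gaussian detector noise, as a fraction of the ECM mean
#'   intensity.
#' @param ecm_intensity mean tracer intensity in the ECM, arbitrary units.
#' @param smc_intensity intensity inside SMCs (the tracer is excluded from
#'   cells, so this is near zero).
#' @param seed integer seed.
#' @return an object of class `optics_params`.
#' @export
optics_params <- function(attenuation_length = 150,
                          noise_sd = 0.05,
                          ecm_intensity = 1000,
                          smc_intensity = 30,
                          seed = 1L) {
  if (attenuation_length <= 0) abort("attenuation_length must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (smc_intensity < 0 || smc_intensity >= ecm_intensity) {
    abort("need 0 <= smc_intensity < ecm_intensity")
  }
  structure(
    list(attenuation_length = attenuation_length, noise_sd = noise_sd,
         ecm_intensity = ecm_intensity, smc_intensity = smc_intensity,
         seed = as.integer(seed)),
    class = "optics_params")
}

new_image_stack <- function(intensities, voxel_size, imaging_axis = 1L,
                            meta = list()) {
  if (any(intensities < 0)) abort("intensities must be non-negative")
  structure(
    list(intensities = intensities, voxel_size = voxel_size,
         imaging_axis = as.integer(imaging_axis), meta = meta),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels @ %s um, depth axis %d\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "),
    x$imaging_axis))
  invisible(x)
}

#' Render a fluorescence stack from a labeled microstructure
#'
#' The fluorescent tracer permeates the ECM but is excluded from SMCs, so
#' ECM voxels take `ecm_intensity` and SMC voxels `smc_intensity`. Both are
#' attenuated by `exp(-depth / attenuation_length)` along the imaging axis
#' (the radial axis: synthetic stacks are generated pre-aligned), then
#' Gaussian detector noise is added and negative values are clipped at 0.
#'
#' @param block a `voxel_microstructure`.
#' @param optics an [optics_params()] object.
#' @return an `image_stack`; `meta$attenuation_length` records the true
#'   decay length.
#' @export
generate_fluorescence_stack <- function(block, optics) {
  stopifnot(inherits(block, "voxel_microstructure"),
            inherits(optics, "optics_params"))
  set.seed(optics$seed)
  dims <- dim(block$labels)
  base <- ifelse(block$labels == 1L, optics$smc_intensity,
                 optics$ecm_intensity)
  depth <- voxel_centres(dims[1], block$voxel_size)
  att <- exp(-depth / optics$attenuation_length)
  img <- base * array(att, dims)  # depth varies along axis 1: recycling is exact
  if (optics$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, optics$noise_sd * optics$ecm_intensity)
    img[img < 0] <- 0
  }
  new_image_stack(array(img, dims), rep(block$voxel_size, 3),
                  imaging_axis = 1L,
                  meta = list(attenuation_length = optics$attenuation_length,
                              ecm_intensity = optics$ecm_intensity,
                              smc_intensity = optics$smc_intensity))
}

#' Generate a synthetic bubble-displacement trace
#'
#' In the ex vivo conductance measurement, transmural water flux pushes an
#' air bubble along a graduated capillary; the steady displacement rate
#' gives the volumetric flow. For a wall of hydraulic conductance L_p,
#' surface area A and transmural pressure delta_p, the bubble in a
#' capillary of inner diameter D advances at
#' `L_p * A * delta_p / (pi D^2 / 4)` metres per second. Gaussian reading
#' noise is added to the displacements.
#'
#' @param true_lp hydraulic conductance, m s^-1 Pa^-1.
#' @param surface_area wall surface area A, m^2.
#' @param capillary_diameter capillary inner diameter D, m (the study
#'   apparatus used 460 um).
#' @param delta_p transmural pressure, Pa.
#' @param duration trace length, s (conductance was read over 25 min).
#' @param n_samples number of displacement readings (at least 3).
#' @param noise_sd absolute sd of displacement reading noise, m.
#' @param seed integer seed.
#' @return a tibble of class `bubble_trace` with columns `time` (s) and
#'   `displacement` (m); capillary diameter, area, pressure and the true
#'   L_p are carried as attributes.
#' @export
generate_bubble_trace <- function(true_lp, surface_area,
                                  capillary_diameter = 460e-6,
                                  delta_p = mmHg_to_Pa(100),
                                  duration = 1500, n_samples = 50L,
                                  noise_sd = 0, seed = 1L) {
  if (true_lp < 0) abort("true_lp must be >= 0")
  if (surface_area <= 0 || capillary_diameter <= 0 || delta_p <= 0 ||
      duration <= 0) {
    abort("surface_area, capillary_diameter, delta_p, duration must be > 0")
  }
  if (n_samples < 3) abort("need at least 3 samples")
  set.seed(seed)
  times <- seq(0, duration, length.out = n_samples)
  slope <- true_lp * surface_area * delta_p / (pi * capillary_diameter^2 / 4)
  disp <- slope * times
  if (noise_sd > 0) disp <- disp + rnorm(n_samples, 0, noise_sd)
  out <- tibble(time = times, displacement = disp)
  class(out) <- c("bubble_trace", class(out))
  attr(out, "capillary_diameter") <- capillary_diameter
  attr(out, "surface_area") <- surface_area
  attr(out, "delta_p") <- delta_p
  attr(out, "true_lp") <- true_lp
  out
}

#' Generate a synthetic (J, k) constitutive dataset
#'
#' Evaluates the deformation-dependent permeability law at the supplied
#' volumetric ratios and applies multiplicative lognormal noise, emulating
#' the scatter of block-wise homogenized permeabilities.
#'
#' @param params a [constitutive_params()] object.
#' @param j_grid volumetric ratios J; all must exceed `params$phi_s_ref`
#'   (at the reference solid fraction the pores are closed).
#' @param noise_sd sdlog of the multiplicative lognormal noise.
#' @param seed integer seed.
#' @return a tibble with columns `J` and `k` (permeability in the law's
#'   scale units).
#' @export
generate_constitutive_dataset <- function(params, j_grid, noise_sd = 0.01,
                                          seed = 1L) {
  stopifnot(inherits(params, "constitutive_params"))
  if (any(j_grid <= params$phi_s_ref)) {
    abort("all J must exceed phi_s_ref (pore-closure bound)")
  }
  set.seed(seed)
  k <- constitutive_eval(j_grid, params)
  if (noise_sd > 0) k <- k * exp(rnorm(length(k), 0, noise_sd))
  tibble(J = j_grid, k = k)
}
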