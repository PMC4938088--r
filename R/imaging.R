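#' Correct depth attenuation in a fluorescence stack
#'
#' Confocal intensity decays with imaging depth (scattering and
#' absorption). A single-exponential model is fitted to the per-plane mean
#' intensity of ECM-candidate voxels (the top intensity quartile of each
#' plane, which is matrix so long as cells occupy less than three quarters
#' of the plane) and divided out, so that corrected plane means are flat
#' across depth.
#'
#' @param stack an `image_stack` with at least 4 depth planes.
#' @return a corrected `image_stack`; `meta$fitted_attenuation_length`
#'   holds the estimated decay length (um), or `Inf` when no decay was
#'   detected and the stack was returned unchanged (with a warning).
#' @export
correct_attenuation <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  ax <- stack$imaging_axis
  img <- stack$intensities
  nd <- dim(img)[ax]
  if (nd < 4) abort("need at least 4 depth planes")
  if (all(img == 0)) abort("all-zero stack: nothing to correct")
  # plane means over ECM-candidate voxels: the top intensity quartile is
  # matrix even in cell-rich planes (SMC fractions stay below 75 percent)
  planes <- apply(img, ax, function(p) mean(p[p >= quantile(p, 0.75)]))
  depth <- voxel_centres(nd, stack$voxel_size[ax])
  ok <- planes > 0
  if (sum(ok) < 4) abort("too few non-empty planes for an attenuation fit")
  fit <- lm(log(planes[ok]) ~ depth[ok])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) {
    warn("no depth decay detected; returning stack uncorrected")
    stack$meta$fitted_attenuation_length <- Inf
    return(stack)
  }
  len <- -1 / slope
  corr <- exp(depth / len)  # undo exp(-depth/len)
  shape <- rep(1L, 3)
  shape[ax] <- nd
  img <- img * array(aperm(array(corr, dim(img)[c(ax, setdiff(1:3, ax))]),
                           order(c(ax, setdiff(1:3, ax)))), dim(img))
  stack$intensities <- img
  stack$meta$fitted_attenuation_length <- unname(len)
  stack
}

# quarter-turn rotation of a 3D array about one axis (k quarter turns,
# right-handed looking down the axis)
rot3d90 <- function(a, axis, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(a)
  perm <- switch(axis,
                 `1` = c(1, 3, 2),
                 `2` = c(3, 2, 1),
                 `3` = c(2, 1, 3))
  flip <- switch(axis, `1` = 2L, `2` = 3L, `3` = 1L)
  for (q in seq_len(k)) {
    a <- aperm(a, perm)
    idx <- rep(list(quote(expr = )), 3)
    idx[[flip]] <- rev(seq_len(dim(a)[flip]))
    a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  a
}

#' Align stack axes by quarter-turn rotations
#'
#' Applies a sequence of 90-degree rotations (as done when aligning raw
#' confocal stacks to the cylindrical coordinates of the vessel, so that
#' axis 1 becomes the radial direction). Voxel sizes are permuted
#' consistently.
#'
#' @param stack an `image_stack`.
#' @param rotations a list of `c(axis, quarter_turns)` pairs, applied in
#'   order.
#' @return the rotated `image_stack`.
#' @export
align_axes <- function(stack, rotations = list()) {
  stopifnot(inherits(stack, "image_stack"))
  img <- stack$intensities
  vs <- stack$voxel_size
  ia <- stack$imaging_axis
  for (r in rotations) {
    axis <- as.integer(r[1]); k <- as.integer(r[2])
    img <- rot3d90(img, axis, k)
    if (k %% 2 == 1) {
      perm <- switch(axis, `1` = c(1, 3, 2), `2` = c(3, 2, 1), `3` = c(2, 1, 3))
      vs <- vs[perm]
      ia <- match(ia, perm)
    }
  }
  stack$intensities <- img
  stack$voxel_size <- vs
  stack$imaging_axis <- ia
  stack
}

# Otsu's threshold: maximizes between-class variance of the intensity
# histogram.  (Computed directly on a 256-bin histogram; installed image
# packages only offer per-2D-frame thresholds.)
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  bc <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' Segment SMCs from a fluorescence stack by thresholding
#'
#' The tracer is excluded from cells, so voxels below the threshold are
#' labeled SMC and voxels above it ECM. The default threshold is Otsu's
#' criterion on the (corrected) intensity histogram; a manual threshold can
#' be supplied to mirror observer-chosen thresholds.
#'
#' @param stack an `image_stack`, ideally attenuation-corrected.
#' @param method `"otsu"` (default) or `"manual"`.
#' @param manual_threshold intensity threshold when `method = "manual"`.
#' @return a `voxel_microstructure` (labels 1 = SMC, 0 = ECM) with the
#'   threshold recorded in `attr(, "threshold")`. Warns when the histogram
#'   shows no clear bimodality.
#' @export
segment_smc <- function(stack, method = c("otsu", "manual"),
                        manual_threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  x <- stack$intensities
  thr <- if (method == "manual") {
    if (is.null(manual_threshold)) abort("manual method needs manual_threshold")
    manual_threshold
  } else {
    otsu_threshold(as.vector(x))
  }
  lab <- array(0L, dim(x))
  lab[x < thr] <- 1L
  # bimodality diagnostic: fraction of the intensity variance explained by
  # the two-class split (Otsu's criterion value). A unimodal histogram cut
  # at its mode explains about 0.64; clean two-level stacks explain > 0.9.
  in1 <- x[lab == 1L]; in2 <- x[lab == 0L]
  if (length(in1) > 1 && length(in2) > 1 && stats::var(as.vector(x)) > 0) {
    w1 <- length(in1) / length(x)
    eta <- w1 * (1 - w1) * (mean(in2) - mean(in1))^2 / stats::var(as.vector(x))
    if (eta < 0.75) {
      warn(sprintf(
        "threshold explains only %.0f%% of intensity variance: histogram may be unimodal",
        100 * eta))
    }
  }
  out <- new_voxel_microstructure(lab, stack$voxel_size[1])
  attr(out, "threshold") <- thr
  out
}

#' SMC and ECM volume fractions of a labeled block
#'
#' Simple voxel counting: `phi_smc + phi_ecm = 1` exactly.
#'
#' @param block a `voxel_microstructure`.
#' @return a one-row tibble with `phi_smc` and `phi_ecm`.
#' @export
volume_fractions <- function(block) {
  stopifnot(inherits(block, "voxel_microstructure"))
  phi <- mean(block$labels == 1L)
  tibble(phi_smc = phi, phi_ecm = 1 - phi)
}

#' Radial morphometrics of a labeled block
#'
#' Runs one-voxel lines along the radial axis (axis 1) through every
#' transverse position and run-length encodes the labels. The SMC layer
#' count is the mean number of SMC runs per line, the mean SMC radial
#' width is total SMC length over number of runs, and the ECM radial
#' thickness is the mean summed ECM run length per line (the summed
#' inter-cell distances). Runs touching the block boundary are included.
#' Given a reference block, the ECM compression percentage between the two
#' states is also reported.
#'
#' @param block a `voxel_microstructure` with at least 4 radial voxels.
#' @param reference optional reference-state `voxel_microstructure`.
#' @return a one-row tibble: `n_smc_layers_radial`,
#'   `mean_smc_radial_width` (um, `NA` if the block holds no SMC),
#'   `ecm_radial_thickness` (um), `ecm_compression_pct` (`NA` without a
#'   reference).
#' @export
radial_metrics <- function(block, reference = NULL) {
  stopifnot(inherits(block, "voxel_microstructure"))
  dims <- dim(block$labels)
  if (dims[1] < 4) abort("block thinner than 4 voxels radially")
  h <- block$voxel_size
  lab <- block$labels
  lines <- matrix(lab, nrow = dims[1])  # columns are radial lines
  runs <- apply(lines, 2, function(v) {
    r <- rle(v)
    c(n_smc_runs = sum(r$values == 1L),
      smc_len = sum(r$lengths[r$values == 1L]),
      ecm_len = sum(r$lengths[r$values == 0L]))
  })
  n_runs_total <- sum(runs["n_smc_runs", ])
  n_layers <- mean(runs["n_smc_runs", ])
  width <- if (n_runs_total > 0) {
    sum(runs["smc_len", ]) * h / n_runs_total
  } else {
    warn("block contains no SMC voxels; mean width undefined")
    NA_real_
  }
  ecm_thick <- mean(runs["ecm_len", ]) * h
  comp <- NA_real_
  if (!is.null(reference)) {
    ref <- radial_metrics(reference)
    comp <- 100 * (1 - ecm_thick / ref$ecm_radial_thickness)
  }
  tibble(n_smc_layers_radial = n_layers,
         mean_smc_radial_width = width,
         ecm_radial_thickness = ecm_thick,
         ecm_compression_pct = comp)
}
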