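#' Plot a resistance decomposition
#'
#' Wall, medial and intimal resistance curves against transmural pressure,
#' with the ECM-permeability uncertainty bands and the crossover pressure
#' marked.
#'
#' @param object a `resistance_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.resistance_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("pressure", "r_wall", "r_med", "r_int")],
    -"pressure", names_to = "layer", values_to = "resistance")
  cross <- attr(object, "crossover")
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(.data$pressure, .data$resistance,
                                     colour = .data$layer)) +
    ggplot2::geom_ribbon(
      data = as_tibble(object),
      ggplot2::aes(x = .data$pressure, ymin = .data$r_med_lo,
                   ymax = .data$r_med_hi),
      inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_ribbon(
      data = as_tibble(object),
      ggplot2::aes(x = .data$pressure, ymin = .data$r_int_lo,
                   ymax = .data$r_int_hi),
      inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "transmural pressure (mmHg)",
                  y = "hydraulic resistance (Pa s/m)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(cross) > 0) {
    gg <- gg + ggplot2::geom_vline(xintercept = cross$crossover_mmHg,
                                   linetype = "dashed", colour = "grey40")
  }
  gg
}

#' Plot a sigmoid fit over its data
#'
#' @param object a `sigmoid_fit`.
#' @param n_curve points on the fitted curve.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, n_curve = 200L, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = n_curve))
  grid$y <- object$fn(grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::theme_minimal()
}

#' Plot a constitutive fit over its data
#'
#' @param object a `constitutive_fit`.
#' @param n_curve points on the fitted curve.
#' @param log_k plot permeability on a log scale.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.constitutive_fit <- function(object, n_curve = 300L, log_k = TRUE,
                                      ...) {
  grid <- tibble(J = seq(min(object$data$J), max(object$data$J),
                         length.out = n_curve))
  grid$k <- constitutive_eval(grid$J, object$params)
  gg <- ggplot2::ggplot(object$data, ggplot2::aes(.data$J, .data$k)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "volumetric ratio J", y = "radial permeability k") +
    ggplot2::theme_minimal()
  if (log_k) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Mid-block slice of a labeled microstructure
#'
#' @param block a `voxel_microstructure`.
#' @param axis slicing axis (default 3: a radial-transverse section).
#' @param index slice index (defaults to the mid-plane).
#' @return a ggplot raster of the SMC/ECM labels.
#' @export
plot_slice <- function(block, axis = 3L, index = NULL) {
  stopifnot(inherits(block, "voxel_microstructure"))
  dims <- dim(block$labels)
  if (is.null(index)) index <- ceiling(dims[axis] / 2)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- index
  sl <- do.call(`[`, c(list(block$labels), idx, list(drop = TRUE)))
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$label <- ifelse(as.vector(sl) == 1L, "SMC", "ECM")
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(ECM = "palegreen3",
                                          SMC = "steelblue4")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = "radial voxel", fill = NULL) +
    ggplot2::theme_minimal()
}
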