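# broom-style accessors and plots for fitted objects

#' Tidy a single-voxel fit
#'
#' @param x A `voxel_fit` from [fit_voxel()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `model`
#'   (mono/bi), `term`, `estimate`.
#' @export
tidy.voxel_fit <- function(x, ...) {
  rows <- list()
  if (!is.null(x$mono$params)) {
    p <- x$mono$params
    rows$mono <- tibble::tibble(model = "mono",
                                term = c("S0", "T_mono"),
                                estimate = c(p$S0, p$T_mono))
  }
  if (!is.null(x$bi$params)) {
    p <- x$bi$params; fr <- x$bi$fractions
    rows$bi <- tibble::tibble(
      model = "bi",
      term = c("S0", "T_short", "T_long", "F_short", "F_long"),
      estimate = c(p$S0, p$T_s, p$T_l, fr$F_s, fr$F_l))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a single-voxel fit
#'
#' @param x A `voxel_fit`.
#' @param ... Unused.
#' @return A one-row tibble (same columns as a [fit_voxels()] row).
#' @export
glance.voxel_fit <- function(x, ...) {
  tidy_voxel_fit(x)
}

#' @export
tidy.parameter_maps <- function(x, ...) as_tibble(x)

#' One-row summary of a fitted volume
#'
#' @param x A `parameter_maps` object.
#' @param ... Unused.
#' @return A one-row tibble: voxel counts, percent of fitted voxels with a
#'   detected (retained) biexponential decay, percent excluded by the
#'   separation rule, and the ROI-free map means.
#' @export
glance.parameter_maps <- function(x, ...) {
  lin <- which(x$tissue_mask)
  tibble::tibble(
    modality = x$modality,
    n_fitted = x$n_fitted,
    n_failed = x$n_failed,
    pct_bi_detected = 100 * mean(x$bi_detected[lin], na.rm = TRUE),
    pct_excluded = 100 * mean(x$exclusion_mask[lin], na.rm = TRUE),
    T_mono_mean = mean(x$T_mono[lin], na.rm = TRUE),
    T_short_mean = mean(x$T_short[lin], na.rm = TRUE),
    T_long_mean = mean(x$T_long[lin], na.rm = TRUE),
    F_short_mean = mean(x$F_short[lin], na.rm = TRUE))
}

#' Plot a voxel's decay and both fitted models
#'
#' Measured samples with the mono- and biexponential fitted curves, on a
#' log signal axis (a monoexponential decay is a straight line there, so
#' curvature reveals a second component).
#'
#' @param object A `voxel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_fit <- function(object, ...) {
  tt <- seq(min(object$times), max(object$times), length.out = 200)
  curves <- list()
  if (!is.null(object$mono$params)) {
    curves$mono <- tibble::tibble(time = tt, model = "mono",
                                  signal = mono_signal(tt, object$mono$params))
  }
  if (!is.null(object$bi$params)) {
    curves$bi <- tibble::tibble(time = tt, model = "bi",
                                signal = bi_signal(tt, object$bi$params))
  }
  pts <- tibble::tibble(time = object$times, signal = object$signal)
  ggplot2::ggplot(dplyr::bind_rows(curves),
                  ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_point(data = pts, shape = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ms)", y = "signal", colour = NULL,
                  subtitle = sprintf("verdict: %s", object$verdict)) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a parameter map
#'
#' @param object A `parameter_maps` object.
#' @param map Which map to draw.
#' @param slice Slice index along z.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parameter_maps <- function(object,
                                    map = c("T_mono", "T_short", "T_long",
                                            "F_short", "F_long",
                                            "exclusion_mask", "bi_detected"),
                                    slice = 1, ...) {
  map <- match.arg(map)
  m <- object[[map]][, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = map, title = sprintf("%s, slice %d", map, slice)) +
    ggplot2::theme_minimal()
}
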