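#' Heatmap of cross-validation performance
#'
#' Median test MSE (or R^2) per anchor cell, one tile per (rotation,
#' slice), faceted by boundary and model variant — the standard summary
#' view of where on the ventricle each model struggles (typically the
#' basal posterior septum under the shadow artifact).
#'
#' @param object A `cv_result`.
#' @param metric `"median_mse"` or `"median_r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, metric = c("median_mse", "median_r2"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$heatmap, ggplot2::aes(
    x = factor(.data$z_frac), y = factor(.data$theta_deg),
    fill = .data[[metric]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(boundary ~ variant,
                        labeller = ggplot2::labeller(variant = function(v) paste0("Model ", v))) +
    ggplot2::scale_fill_viridis_c(name = if (metric == "median_mse") {
      expression("median MSE (mm"^2 * ")")
    } else expression("median R"^2)) +
    ggplot2::labs(x = "apex-to-base fraction", y = "rotation (deg)") +
    ggplot2::theme_minimal()
}

#' Strain curves over the cardiac cycle
#'
#' @param strain Output of [circumferential_strain()] or
#'   [longitudinal_strain()].
#' @param by Grouping column (`"z_frac"` for circumferential,
#'   `"theta_deg"` for longitudinal); guessed from the columns present.
#' @return A ggplot object.
#' @export
plot_strain_curves <- function(strain, by = NULL) {
  if (is.null(by)) by <- if ("z_frac" %in% names(strain)) "z_frac" else "theta_deg"
  ggplot2::ggplot(strain, ggplot2::aes(
    x = .data$phase, y = .data$strain,
    colour = factor(.data[[by]]), group = .data[[by]]
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle phase", y = "Lagrangian strain", colour = by) +
    ggplot2::theme_minimal()
}

#' Short-axis contours of a mesh at one z level
#'
#' @param object An `lv_mesh`.
#' @param z_frac Apex-to-base fraction to display.
#' @param t_index Time samples to overlay (default: end-diastole and the
#'   volume-based peak systole).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lv_mesh <- function(object, z_frac = 0.5, t_index = NULL, ...) {
  if (is.null(t_index)) {
    gf <- global_function(object)
    t_index <- unique(c(1L, which.min(abs(object$time_samples - gf$ps_phase))))
  }
  zz <- which.min(abs(object$z_samples - z_frac))
  th <- object$angle_samples * pi / 180
  df <- purrr::map_dfr(t_index, function(tt) {
    purrr::map_dfr(1:2, function(b) {
      r <- object$radii[b, , zz, tt]
      tibble(boundary = ANCHOR_BOUNDARIES[b], phase = object$time_samples[tt],
             x = c(r * cos(th), r[1] * cos(th[1])),
             y = c(r * sin(th), r[1] * sin(th[1])))
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$boundary,
                                   linetype = factor(round(.data$phase, 3)))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", linetype = "phase") +
    ggplot2::theme_minimal()
}
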