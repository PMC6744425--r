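#' Plot distance-behavior correlations with their noise ceiling
#'
#' Bars of the group mean correlation per category with per-subject points and
#' the (sign-inverted) joint reliability ceiling, for every completed
#' ROI x task cell of a pipeline run.
#'
#' @param object An `ndba_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ndba_run <- function(object, ...) {
  per_subject <- purrr::map_dfr(object$results, tidy)
  summary <- object$summary
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$mean_r)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = -.data$joint_reliability, ymax = -.data$joint_reliability),
      linewidth = 2, colour = "grey70", width = 0.45, na.rm = TRUE) +
    ggplot2::geom_jitter(data = per_subject,
                         ggplot2::aes(y = .data$r), width = 0.08, alpha = 0.5,
                         size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(roi ~ task, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "distance-behavior correlation (r)",
                  caption = "grey bars: sign-inverted joint reliability ceiling") +
    ggplot2::theme_minimal()
}

#' Plot distance-behavior correlations for one analysis cell
#'
#' @param object An `ndba_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ndba_result <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$category, y = .data$mean_r)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_jitter(data = object$per_subject, ggplot2::aes(y = .data$r),
                         width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(title = sprintf("task %s, %s", object$task, object$roi),
                  x = NULL, y = "r") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a searchlight accuracy map
#'
#' @param accuracy Numeric per-voxel map or `[subject x voxel]` matrix.
#' @param voxel_coords Integer `[voxel x 3]` coordinates.
#' @param z Slice to show (default: middle slice).
#' @param roi Optional voxel indices outlined as the selected ROI.
#' @return A ggplot object.
#' @export
plot_searchlight_slice <- function(accuracy, voxel_coords, z = NULL, roi = NULL) {
  m <- searchlight_map(accuracy, voxel_coords)
  if (is.null(z)) z <- round(stats::median(m$z))
  sl <- dplyr::filter(m, .data$z == !!z)
  sl$in_roi <- sl$voxel %in% (roi %||% integer(0))
  ggplot2::ggplot(sl, ggplot2::aes(.data$x, .data$y, fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(sl, .data$in_roi), fill = NA,
                       colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(limits = c(0.25, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("searchlight accuracy, z = %d", z)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang %||%
NULL
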