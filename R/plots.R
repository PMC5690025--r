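#' Plot a phantom-section image
#'
#' @param object A [section_image][new_section_image].
#' @param ... Unused.
#' @return A ggplot raster of the pixel grid in mm coordinates.
#' @method autoplot section_image
#' @export
autoplot.section_image <- function(object, ...) {
  df <- raster_df(object$pixels, object$spacing_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      title = sprintf("%s section (%s)", object$section_kind,
                      class_key(object$labels)),
      x = "x (mm)", y = "y (mm)", fill = "intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Winston-Lutz image with both detected centres
#'
#' @param object A [wl_image][generate_wl_image].
#' @param result Optional [analyze_wl_image()] row; when supplied the field
#'   (cross) and BB (circle) centres are overlaid for visual inspection.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wl_image
#' @export
autoplot.wl_image <- function(object, result = NULL, ...) {
  df <- raster_df(object$pixels, object$spacing_mm)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("Winston-Lutz %s", object$id),
                  x = "x (mm)", y = "y (mm)", fill = "level") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    size <- nrow(object$pixels); c0 <- (size + 1) / 2
    ctr <- tibble::tibble(
      x_mm = (c(result$field_col, result$bb_col) - c0) * object$spacing_mm,
      y_mm = (c(result$field_row, result$bb_row) - c0) * object$spacing_mm,
      which = c("field", "BB")
    )
    p <- p + ggplot2::geom_point(
      data = ctr,
      ggplot2::aes(.data$x_mm, .data$y_mm, colour = .data$which, shape = .data$which),
      inherit.aes = FALSE, size = 3, stroke = 1.2
    ) +
      ggplot2::scale_shape_manual(values = c(field = 3, BB = 1)) +
      ggplot2::scale_colour_manual(values = c(field = "red", BB = "cyan"))
  }
  p
}

#' Plot an MTF curve
#'
#' @param mtf Result of [compute_mtf()] (or its `curve` tibble).
#' @return A ggplot of modulation vs spatial frequency, with the 50% and 10%
#'   levels marked.
#' @export
plot_mtf_curve <- function(mtf) {
  curve <- if (is.data.frame(mtf)) mtf else mtf$curve
  ggplot2::ggplot(curve, ggplot2::aes(.data$freq_lpcm, .data$mtf)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.5, 0.1), linetype = "dashed") +
    ggplot2::labs(x = "frequency (lp/cm)", y = "MTF") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-validation errors per section and class head
#'
#' @param object An [artifact_classifier][train_artifact_classifier].
#' @param ... Unused.
#' @return A ggplot tile map of CV error by section kind and class.
#' @method autoplot artifact_classifier
#' @export
autoplot.artifact_classifier <- function(object, ...) {
  ggplot2::ggplot(
    object$heads,
    ggplot2::aes(.data$section_kind, .data$class, fill = .data$cv_error)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$cv_error))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CV error") +
    ggplot2::theme_minimal()
}

raster_df <- function(pixels, spacing_mm) {
  size <- nrow(pixels); c0 <- (size + 1) / 2
  tibble::tibble(
    x_mm = rep((seq_len(size) - c0) * spacing_mm, each = size),
    y_mm = rep((seq_len(size) - c0) * spacing_mm, times = size),
    value = as.vector(pixels)
  )
}
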