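#' Plot a mean spectrum per group
#'
#' @param pool pixel-pool tibble.
#' @param group grouping column (default `"exposed"`).
#' @return A ggplot: absorbance vs wavenumber (axis reversed, the
#'   spectroscopic convention), one line per group.
#' @export
plot_group_spectra <- function(pool, group = "exposed") {
  gm <- group_mean_spectra(pool, group)
  axis <- attr(gm, "axis")
  df <- purrr::map(seq_len(nrow(gm)), function(i) {
    tibble::tibble(group = as.character(gm[[group]][i]),
                   wavenumber = axis,
                   absorbance = gm$spectrum[i, ])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance",
                  color = group) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object a `radsig_eval`.
#' @param ... unused.
#' @return A ggplot of the sample-level ROC curve with its AUC in the
#'   subtitle.
#' @export
autoplot.radsig_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Sample-level ROC (%s)", object$family %||% ""),
      subtitle = sprintf("AUC = %.3f", object$overall$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Embedding scatter plot
#'
#' @param object a `radsig_embedding`.
#' @param color optional vector (length = pixels) to color by, e.g. dose.
#' @param ... unused.
#' @return A ggplot of the 2-D embedding; rejected pixels are crossed out.
#' @export
autoplot.radsig_embedding <- function(object, color = NULL, ...) {
  df <- tibble::tibble(x = object$coords[, 1], y = object$coords[, 2],
                       accepted = object$accepted)
  if (!is.null(color)) df$color <- as.character(color)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = "Embedding 1", y = "Embedding 2") +
    ggplot2::theme_minimal()
  p <- if (is.null(color)) {
    p + ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$color,
                                         shape = .data$accepted), size = 0.8)
  }
  p + ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4))
}

#' Specificity-by-day bar plot
#'
#' Mirrors the standard presentation of time-resolved detectability: one
#' bar per day post-exposure, height = specificity at the given sensitivity
#' pin.
#'
#' @param eval_report a `radsig_eval` from [stratified_report()].
#' @param sens sensitivity pin (must match one used in the report).
#' @return A ggplot.
#' @export
plot_day_specificity <- function(eval_report, sens = 0.9) {
  col <- sprintf("spec_at_sens_%g", sens)
  if (!col %in% names(eval_report$by_day)) {
    stop(sprintf("report has no specificity column at sensitivity %g", sens),
         call. = FALSE)
  }
  df <- eval_report$by_day
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$day), .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Days post-exposure",
                  y = sprintf("Specificity at %.0f%% sensitivity", 100 * sens)) +
    ggplot2::theme_minimal()
}

#' Detector mask image
#'
#' @param mask a [pixel_mask()].
#' @return A ggplot tile image of accepted/rejected pixels.
#' @export
plot_mask <- function(mask) {
  d <- dim(mask$accepted)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    accepted = as.vector(mask$accepted)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$accepted)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = mask$provenance, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
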