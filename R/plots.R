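#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Profile spectra are drawn as a line trace, centroid spectra as sticks.
#'
#' @param object A `glyq_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glyq_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity))
  p <- if (spectrum_mode(object) == "profile") {
    p + ggplot2::geom_line(linewidth = 0.3)
  } else {
    p + ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                              linewidth = 0.4)
  }
  p + ggplot2::labs(x = "m/z", y = "intensity") + ggplot2::theme_minimal()
}

#' Plot a theoretical isotope pattern
#'
#' @param object A `glyq_pattern`.
#' @param ... Unused.
#' @return A ggplot object; the apex isotopologue is highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.glyq_pattern <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$isotope, y = .data$abundance,
                                   fill = .data$apex)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "isotope (1-based)", y = "relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run: spectrum with matched envelope monos marked
#'
#' @param object A `glyq_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glyq_run <- function(object, ...) {
  p <- autoplot(object$spectrum)
  if (nrow(object$matches)) {
    ann <- object$matches |>
      dplyr::group_by(.data$envelope) |>
      dplyr::slice_min(abs(.data$error_ppm), n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    ymax <- max(object$spectrum$intensity)
    p <- p +
      ggplot2::geom_point(data = ann,
                          ggplot2::aes(x = .data$observed_mz,
                                       y = ymax * 1.02),
                          inherit.aes = FALSE, shape = 25,
                          fill = "firebrick", size = 2) +
      ggplot2::geom_text(data = ann,
                         ggplot2::aes(x = .data$observed_mz,
                                      y = ymax * 1.06,
                                      label = paste0(.data$composition,
                                                     " [", .data$channel,
                                                     "]")),
                         inherit.aes = FALSE, size = 2.5, angle = 90,
                         hjust = 0)
  }
  p
}
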