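#' Plot a density profile with optional peak annotations
#'
#' @param object a `density_profile` from [collapse_profile()].
#' @param peaks optional peak tibble from [detect_peaks()]; labelled peaks
#'   are marked and annotated.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_center, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from membrane midplane (nm, cytoplasm positive)",
      y = "mean density"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p +
      ggplot2::geom_vline(data = peaks,
                          ggplot2::aes(xintercept = .data$center),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::geom_point(data = peaks,
                          ggplot2::aes(x = .data$center, y = .data$height),
                          colour = "firebrick")
    if (!all(is.na(peaks$label))) {
      lp <- peaks[!is.na(peaks$label), ]
      p <- p + ggplot2::annotate("text", x = lp$center,
                                 y = lp$height, label = lp$label,
                                 vjust = -0.8, size = 3)
    }
  }
  p
}

#' Bar plot of per-column information content from logo data
#'
#' @param logo_data output of [cterm_logo()].
#' @return A ggplot of information content (bits) per column, with the
#'   consensus residue printed above each bar.
#' @export
plot_logo <- function(logo_data) {
  cols <- logo_data |>
    group_by(.data$column) |>
    summarise(
      ic_bits = .data$ic_bits[1],
      top = if (all(is.na(.data$residue))) NA_character_ else
        .data$residue[which.max(.data$frequency)],
      .groups = "drop"
    )
  ggplot2::ggplot(cols, ggplot2::aes(x = .data$column, y = .data$ic_bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$top), vjust = -0.4,
                       size = 3, na.rm = TRUE) +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::ylim(0, log2(20) * 1.1) +
    ggplot2::theme_minimal()
}

#' Dot plot of measured layer distances with expanded uncertainties
#'
#' @param object a `layer_report` from [measure_layers()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot layer_report
#' @export
autoplot.layer_report <- function(object, ...) {
  d <- object$distances
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$distance_nm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$distance_nm - .data$expanded_uncertainty_nm,
                   ymax = .data$distance_nm + .data$expanded_uncertainty_nm),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("distance from %s peak (nm, k = %g)",
                  object$reference_peak,
                  if (nrow(d)) d$k[1] else NA_real_)
    ) +
    ggplot2::theme_minimal()
}
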