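#' Plot a radial migration histogram
#'
#' Draws the assay's standard readout: pixel counts per radial-distance bin,
#' with collective migration as grey bars and single-cell migration as black
#' bars, side by side per bin.
#'
#' @param object a `migration_histogram` or `migration_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot migration_histogram
#' @export
autoplot.migration_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df,
    cols = c("collective_pixels", "single_pixels"),
    names_to = "class", values_to = "pixels"
  )
  long$class <- ifelse(long$class == "collective_pixels",
    "collective", "single cell"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$pixels, fill = .data$class
  )) +
    ggplot2::geom_col(position = "dodge", width = attr(object, "bin_width") * 0.9) +
    ggplot2::scale_fill_manual(values = c(
      "collective" = "grey60",
      "single cell" = "black"
    )) +
    ggplot2::labs(
      x = "migration distance", y = "pixels",
      fill = NULL
    ) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.migration_histogram
#' @method autoplot migration_result
#' @export
autoplot.migration_result <- function(object, ...) {
  autoplot.migration_histogram(object$histogram, ...) +
    ggplot2::ggtitle(object$name)
}

#' Plot per-condition migration summaries
#'
#' Compares collective vs single-cell voxel counts across the conditions of a
#' quantified panel (the output of [quantify_panel()]).
#'
#' @param panel_summary tibble from [quantify_panel()].
#' @return A ggplot object.
#' @export
plot_panel_summary <- function(panel_summary) {
  stopifnot(all(c("condition", "n_collective", "n_single") %in% names(panel_summary)))
  long <- tidyr::pivot_longer(
    dplyr::select(panel_summary, "condition", "n_collective", "n_single"),
    cols = c("n_collective", "n_single"),
    names_to = "class", values_to = "voxels"
  )
  long$class <- ifelse(long$class == "n_collective", "collective", "single cell")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$condition, y = .data$voxels,
    fill = .data$class
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(
      "collective" = "grey60",
      "single cell" = "black"
    )) +
    ggplot2::labs(x = NULL, y = "voxels", fill = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
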