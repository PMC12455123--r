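# ggplot2 display of the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a PCA map
#'
#' Scatter of the first two principal components, coloured by marker
#' class (or assignment when supplied); flagged display outliers are
#' dropped from the panel, never from the data.
#'
#' @param object A `pca_map` from [pca_map()].
#' @param colour_by Optional character vector (e.g. assignments) aligned
#'   with the map rows; defaults to the marker column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_map <- function(object, colour_by = NULL, ...) {
  ve <- attr(object, "var_explained")
  df <- tibble::as_tibble(object)
  df$.colour <- if (!is.null(colour_by)) {
    colour_by
  } else if ("marker" %in% names(df)) {
    df$marker
  } else {
    NA_character_
  }
  df <- df[!df$outlier, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(
      data = df[is.na(df$.colour), ], colour = "grey80", size = 0.6
    ) +
    ggplot2::geom_point(
      data = df[!is.na(df$.colour), ],
      ggplot2::aes(colour = .data$.colour), size = 0.9
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot median marker profiles along the gradient
#'
#' One line per marker class per replicate with a ribbon of plus/minus
#' one standard error, the classic organelle-profile display.
#'
#' @param summary Output of [marker_profile_summary()].
#' @return A ggplot object.
#' @export
plot_marker_profiles <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(.data$fraction, .data$median,
                 colour = .data$marker, fill = .data$marker,
                 group = interaction(.data$marker, .data$replicate))
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$median - .data$se,
                   ymax = .data$median + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = "fraction", y = "relative intensity",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.svm_cv <- function(object, ...) {
  ggplot2::ggplot(object$f1, ggplot2::aes(.data$class, .data$f1)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "held-out F1 per round") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qsep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$reference,
                                   fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "QSep") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
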