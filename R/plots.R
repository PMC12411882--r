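#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot shape-space PCA scores
#'
#' Scatter of two shape components, coloured by group.
#'
#' @param object A `shape_pca` object.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_pca <- function(object, components = c(1L, 2L), ...) {
  stopifnot(length(components) == 2,
            max(components) <= ncol(object$scores))
  df <- tibble::tibble(
    x = object$scores[, components[1]],
    y = object$scores[, components[2]],
    group = object$group
  )
  lab <- function(k) sprintf("shape PC%d (%.1f%%)", k, object$pct_variance[k])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot a ratio spectrum
#'
#' Variables are ordered by position along the spectrum axis; the ratio of
#' the two extreme variables is the most informative for this axis.
#' Bootstrap confidence bounds are drawn when present.
#'
#' @param object A `ratio_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_spectrum <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$position)
  df$variable <- factor(df$variable, levels = df$variable)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$variable))
  if (all(c("ci_lo", "ci_hi") %in% names(df))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2)
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = attr(object, "axis_kind"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the two most discriminating ratios of an LDA ratio extraction
#'
#' Scatter of the best ratio against the second ratio on the original
#' measurement scale, coloured by group.
#'
#' @param object An `lda_ratio` object; the plot needs the measurement table
#'   the extraction was run on.
#' @param data The measurement table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lda_ratio <- function(object, data, ...) {
  data <- data[data$group %in% object$groups, ]
  df <- tibble::tibble(
    x = data[[object$best$numerator]] / data[[object$best$denominator]],
    y = data[[object$second$numerator]] / data[[object$second$denominator]],
    group = data$group
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = object$best$ratio, y = object$second$ratio,
                  colour = "group") +
    ggplot2::theme_minimal()
}
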