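#' Box plots of a feature by group
#'
#' @param data Feature table.
#' @param feature Feature column name.
#' @param group Grouping column name (e.g. `"level"`, `"age_group"`).
#' @param facet_sex Facet by sex if a `sex` column is present.
#' @return A ggplot object.
#' @export
plot_feature_by_group <- function(data, feature, group, facet_sex = FALSE) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = factor(.data[[group]]), y = .data[[feature]])
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = group, y = feature) +
    ggplot2::theme_minimal()
  if (facet_sex && "sex" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~sex)
  }
  p
}

#' Plot one sagittal-like slice of a PDFF map
#'
#' @param map 3D PDFF array.
#' @param mask Optional label mask; outlines are overlaid as tile borders.
#' @param slice Index along the first axis (default: middle).
#' @return A ggplot object.
#' @export
plot_pdff_slice <- function(map, mask = NULL, slice = NULL) {
  dm <- dim(map)
  if (is.null(slice)) slice <- ceiling(dm[1] / 2)
  df <- expand.grid(y = seq_len(dm[2]), z = seq_len(dm[3]))
  df$pdff <- as.vector(map[slice, , ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z, fill = .data$pdff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PDFF [%]", limits = c(0, 100)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    df$label <- as.vector(mask[slice, , ])
    p <- p + ggplot2::geom_tile(
      data = df[df$label > 0, ],
      ggplot2::aes(x = .data$y, y = .data$z),
      fill = NA, colour = "white", linewidth = 0.05, alpha = 0.2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ANOVA result: group means with SD bars
#'
#' @param object An `mtx_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtx_anova <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::labs(
      x = object$group, y = object$feature,
      title = sprintf("F(%d, %.3g) = %.3g, p = %.3g",
                      object$df1, object$df2, object$f_statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot adjusted vs raw sex means
#'
#' @param object An `mtx_glm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtx_glm <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$adjusted_means, c("raw_mean", "adjusted_mean"),
    names_to = "kind", values_to = "mean"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sex, y = .data$mean, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      y = object$feature,
      title = sprintf("sex effect = %.3g (p = %.3g)", object$sex_effect, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
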