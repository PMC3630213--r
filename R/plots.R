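# ggplot2 views of the main result types.

trichome_class_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(`1` = "#d7191c", `2` = "#c51b8a", `3` = "#2b83ba", `4` = "#1a9641"),
    name = "trichome class",
    labels = c("1 initiation", "2 two-branch", "3 three-branch", "4 mature"))
}

#' Plot a meta leaf (pooled, frame-normalized trichome positions)
#' @param object a `metaleaf` tibble.
#' @param ... unused.
#' @export
autoplot.metaleaf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = factor(.data$class))) +
    ggplot2::geom_point(alpha = 0.8) +
    trichome_class_scale() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "baseline x (axis lengths)",
                  y = "longitudinal y (axis tip = 1)") +
    ggplot2::theme_minimal()
}

#' Plot the longitudinal distortion profile with its 50% band
#' @param object a `distortion_map`.
#' @param ... unused.
#' @export
autoplot.distortion_map <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$y, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "longitudinal position (um)",
                  y = "2D/3D area ratio (distortion)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the p-values of a genotype comparison
#' @param object a `genotype_comparison`.
#' @param ... unused.
#' @export
autoplot.genotype_comparison <- function(object, ...) {
  tb <- object$table[object$table$tested, ]
  tb$label <- ifelse(is.na(tb$class), tb$statistic,
                     paste0(tb$statistic, " (class ", tb$class, ")"))
  ggplot2::ggplot(tb, ggplot2::aes(.data$label, .data$p_value)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7191c", `FALSE` = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Wilcoxon p-value") +
    ggplot2::theme_minimal()
}

#' Height map as a filled raster
#' @param object a `height_map`.
#' @param ... unused.
#' @export
autoplot.height_map <- function(object, ...) {
  H <- nrow(object$z_index); W <- ncol(object$z_index)
  df <- tibble::tibble(x = rep(0:(W - 1), each = H),
                       y = rep(0:(H - 1), times = W),
                       z = as.vector(object$z_index))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "z (slice)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
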