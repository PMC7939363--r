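#' Plot a morphology as a 2D projection
#'
#' Projects nodes onto the x-y plane, coloring by the z coordinate (the
#' usual way these epithelial morphologies are displayed).
#'
#' @param m A `morphology`.
#' @param kinds Node kinds to show.
#' @return A ggplot object.
#' @export
plot_morphology <- function(m, kinds = c("epithelial_apical",
                                         "epithelial_basal")) {
  nd <- m$nodes[m$nodes$kind %in% kinds, ]
  ggplot2::ggplot(nd, ggplot2::aes(.data$x, .data$y, colour = .data$z)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = sprintf("t = %.3g", m$time)) +
    ggplot2::theme_minimal()
}

#' Plot a complexity frequency spectrum
#'
#' @param spectrum Tibble from [frequency_spectrum()].
#' @return A ggplot object.
#' @export
plot_frequency_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(.data$mid, .data$frequency)) +
    ggplot2::geom_col(width = min(diff(sort(unique(spectrum$mid)))) * 0.9) +
    ggplot2::labs(x = "complexity", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a mutational asymmetry histogram
#'
#' Parent complexity on x, offspring minus parent complexity on y, shade
#' by log relative abundance within each column.
#'
#' @param hist Tibble from [asymmetry_histogram()].
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(.data$parent_bin, .data$delta_bin,
                                     fill = .data$log_rel_abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "black") +
    ggplot2::labs(x = "parent complexity",
                  y = "offspring - parent complexity",
                  fill = "ln rel. abundance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot GPM regression scatter per parameter
#'
#' @param object A `gpm_regression` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpm_regression <- function(object, ...) {
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    dplyr::mutate(object$points[[i]], param = object$param[i])
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$genetic, .data$morphological)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "genetic distance (%)",
                  y = sprintf("morphological distance (%s)",
                              object$metric[1])) +
    ggplot2::theme_minimal()
}

#' Plot a degeneracy heatmap
#'
#' @param deg Result of [degeneracy_heatmap()].
#' @return A ggplot object.
#' @export
plot_degeneracy <- function(deg) {
  M <- deg$matrix
  df <- tibble::tibble(
    a = rep(rownames(M), ncol(M)),
    b = rep(colnames(M), each = nrow(M)),
    hmd = as.vector(M))
  df$a <- factor(df$a, levels = rownames(M))
  df$b <- factor(df$b, levels = colnames(M))
  ggplot2::ggplot(df[!is.na(df$hmd), ],
                  ggplot2::aes(.data$a, .data$b, fill = .data$hmd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "complexity interval", y = "complexity interval",
                  fill = "mean HMD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
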