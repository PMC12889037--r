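#' Heatmap of a dynamic cross-correlation matrix
#'
#' @param object A `dccm_matrix`.
#' @param ... Unused.
#' @return A ggplot object (blue = anti-correlated, red = correlated).
#' @export
autoplot.dccm_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$residue_i, .data$residue_j,
                                 fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue", fill = "Cᵢⱼ")
}

#' Scatter plot of PCA projections
#'
#' Conformations in PC space, coloured by homolog (joint PCA) or by frame
#' time (single-trajectory PCA); axis labels carry the variance fractions.
#'
#' @param object A `traj_pca`.
#' @param pcs Integer pair of components to plot (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traj_pca <- function(object, pcs = c(1, 2), ...) {
  td <- tidy(object, n_pcs = max(pcs))
  xs <- paste0("PC", pcs[1]); ys <- paste0("PC", pcs[2])
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$variance_fractions[i])
  p <- ggplot2::ggplot(td, ggplot2::aes(.data[[xs]], .data[[ys]]))
  if (length(unique(td$homolog_id)) > 1L) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$homolog_id,
                                              shape = .data$group))
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$time_ns))
  }
  p + ggplot2::labs(x = lab(pcs[1]), y = lab(pcs[2]))
}

#' Box plot of pairwise TM-scores by comparison class
#'
#' @param pair_table A tibble from [pairwise_matrix()].
#' @return A ggplot object.
#' @export
plot_pair_scores <- function(pair_table) {
  ggplot2::ggplot(pair_table,
                  ggplot2::aes(.data$comparison_class, .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "TM-score") +
    ggplot2::ylim(0, 1)
}

#' Conservation-differential profile plot
#'
#' @param profile A tibble from [conservation_differential()].
#' @return A ggplot object of delta against reference position.
#' @export
plot_conservation_delta <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$position, .data$delta)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "reference position",
                  y = "conservation delta (subset - all)")
}

#' Core-residue identification trace plot
#'
#' @param core A `core_find` result.
#' @return A ggplot of the max positional variance against removal step, the
#'   graph from which the core cut is read.
#' @export
plot_core_trace <- function(core) {
  stopifnot(inherits(core, "core_find"))
  ggplot2::ggplot(core$trace,
                  ggplot2::aes(.data$iteration, .data$max_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "removal step", y = "max positional variance (Å²)")
}
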