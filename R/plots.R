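#' Ordination scatter plot
#'
#' First two principal coordinate axes, optionally coloured by population.
#'
#' @param object An `ssr_pcoa` fit.
#' @param pops Optional population label per item (matrix row order) or a
#'   `pop_table()`-style data frame.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_pcoa <- function(object, pops = NULL, ...) {
  df <- object$coordinates
  if (!is.null(pops)) {
    if (is.data.frame(pops)) {
      df$pop <- pops$pop[match(df$id, pops$id)]
    } else {
      df$pop <- pops
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.2f%%)", object$percent[1]),
      y = sprintf("Axis 2 (%.2f%%)", object$percent[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(df$pop)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$pop)) +
      ggplot2::labs(colour = "Population")
  }
}

#' Stacked ancestry bar plot
#'
#' The conventional admixture figure: one bar per individual, segments by
#' posterior-mean cluster ancestry, grouped by population.
#'
#' @param object An `ssr_admixture` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssr_admixture <- function(object, ...) {
  long <- tidy(object)
  long$id <- factor(long$id, levels = unique(object$Q$id[order(object$Q$pop)]))
  ggplot2::ggplot(long, ggplot2::aes(.data$id, .data$ancestry,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~pop, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "Ancestry", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' Evanno delta-K profile
#'
#' @param object An `ssr_evanno` summary.
#' @param ... Unused.
#' @return A ggplot of delta-K against k with the selected k marked.
#' @export
autoplot.ssr_evanno <- function(object, ...) {
  tb <- object$table
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$k, .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
  if (!is.na(object$selected_k)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_k,
                                 linetype = "dashed")
  }
  p
}

#' Plot a UPGMA dendrogram
#'
#' @param x An `ssr_upgma` object.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.ssr_upgma <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
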