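#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot model fit: predicted vs empirical state probabilities
#'
#' Scatter of each observed state's Boltzmann probability under the fitted
#' pairwise model against its empirical occurrence probability, on log-log
#' axes with the identity line; tight clustering around the diagonal
#' indicates a good fit (cf. the accuracy index in the subtitle).
#'
#' @param object A [fit_pmem()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmem_fit <- function(object, ...) {
  k <- as.integer(names(object$stats$state_probs))
  df <- tibble::tibble(
    p_emp = as.numeric(object$stats$state_probs),
    p_mod = state_probabilities(object$params)[k + 1]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_emp, y = .data$p_mod)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "empirical state probability",
                  y = "model state probability",
                  subtitle = sprintf("accuracy index d = %.3f",
                                     object$accuracy_d)) +
    ggplot2::theme_minimal()
}

#' Plot an energy landscape profile
#'
#' Energies of all states in index order with local minima highlighted.
#'
#' @param object An [energy_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$energy)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(data = df[df$is_minimum, ],
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "state index", y = "energy",
                  subtitle = sprintf("%d local minima", sum(df$is_minimum))) +
    ggplot2::theme_minimal()
}

#' Plot a disconnectivity graph
#'
#' Renders the minima merge tree as a dendrogram-style tree: leaves are local
#' minima (labelled by their +/- activity patterns), internal nodes sit at
#' the minimax barrier energies where basins merge.
#'
#' @param object A [disconnectivity_graph()] result with >= 2 minima.
#' @param ... Unused.
#' @return A ggplot object (segments drawn from the tree geometry).
#' @export
autoplot.disconnectivity <- function(object, ...) {
  n_tip <- nrow(object$leaves)
  if (n_tip < 2L)
    stop("autoplot.disconnectivity: need at least 2 minima")
  # leaf x positions follow the phylo plotting order
  tr <- disconnectivity_phylo(object)
  tip_order <- tr$edge[tr$edge[, 2] <= n_tip, 2]
  xpos_leaf <- match(seq_len(n_tip), tip_order)

  node_x <- numeric(nrow(object$merges))
  node_y <- object$merges$height
  segs <- list()
  child_xy <- function(child) {
    if (child < 0) c(xpos_leaf[-child], object$leaves$energy[-child])
    else c(node_x[child], node_y[child])
  }
  for (r in seq_len(nrow(object$merges))) {
    a <- child_xy(object$merges$a[r])
    b <- child_xy(object$merges$b[r])
    node_x[r] <- mean(c(a[1], b[1]))
    y <- object$merges$height[r]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], y), yend = c(y, y, y))
  }
  segs <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(x = xpos_leaf, y = object$leaves$energy,
                           label = object$leaves$pattern)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "energy") +
    ggplot2::theme_minimal()
}

#' Plot basin durations
#'
#' Bar chart of the fraction of simulated time spent in each energy basin.
#'
#' @param durations Tibble from [basin_durations()] (optionally with an
#'   added grouping column `group` for side-by-side cohort comparison).
#' @return A ggplot object.
#' @export
plot_basin_durations <- function(durations) {
  aes <- if ("group" %in% names(durations))
    ggplot2::aes(x = .data$pattern, y = .data$proportion, fill = .data$group)
  else ggplot2::aes(x = .data$pattern, y = .data$proportion)
  ggplot2::ggplot(durations, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "basin (minimum activity pattern)",
                  y = "proportion of simulated time") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
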