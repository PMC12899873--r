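#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_text
#'   geom_errorbarh geom_vline scale_linewidth_continuous labs theme_minimal
#'   theme element_blank
NULL

#' @export
ggplot2::autoplot

# Deterministic Fruchterman-Reingold layout for a ccn object.
ccn_layout <- function(net, seed = 42L) {
  g <- as_igraph(net)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  tibble::tibble(food = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Plot a co-consumption network
#'
#' Positive edges are drawn solid (red), negative edges dashed (blue), with
#' width proportional to `|weight|`; node size reflects degree.
#'
#' @param object A `ccn` object.
#' @param seed Layout seed (default 42).
#' @param label Draw food names (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccn
#' @export
autoplot.ccn <- function(object, seed = 42L, label = TRUE, ...) {
  lay <- ccn_layout(object, seed = seed)
  deg <- igraph::degree(as_igraph(object))
  nodes <- dplyr::mutate(lay, degree = deg[.data$food])
  edges <- object$edges |>
    dplyr::left_join(dplyr::rename(lay, xa = "x", ya = "y"),
                     by = c(food_a = "food")) |>
    dplyr::left_join(dplyr::rename(lay, xb = "x", yb = "y"),
                     by = c(food_b = "food")) |>
    dplyr::mutate(direction = ifelse(.data$weight >= 0,
                                     "positive", "negative"))
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(
      data = edges,
      aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
          linewidth = abs(.data$weight), colour = .data$direction,
          linetype = .data$direction)
    ) +
    geom_point(aes(size = .data$degree), colour = "grey30") +
    ggplot2::scale_colour_manual(
      values = c(positive = "#c23b22", negative = "#2b6ca3")
    ) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed")
    ) +
    scale_linewidth_continuous(range = c(0.2, 1.4)) +
    labs(title = object$group, colour = "correlation",
         linetype = "correlation") +
    theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank())
  if (label) {
    p <- p + geom_text(aes(label = .data$food), size = 2.6, vjust = -1)
  }
  p
}

#' Forest plot of quartile incidence rate ratios
#'
#' @param object Result list from [quartile_irr()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled IRR axis, reference line at 1).
#' @export
plot_irr <- function(object, ...) {
  irr <- object$irr
  ggplot(irr, aes(x = .data$irr, y = .data$term)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.15) +
    geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "Incidence rate ratio (95% CI, robust)",
         y = "D_CCN quartile",
         caption = sprintf("p-trend = %.2g", object$p_trend)) +
    theme_minimal()
}

#' Bar chart of integrated centralities with role colours
#'
#' @param table Output of [centralities()], optionally with `role` from
#'   [classify_roles()] (added if missing).
#' @param top_n Show the `top_n` highest-ranked foods (default 10).
#' @return A ggplot object.
#' @export
plot_centrality <- function(table, top_n = 10) {
  if (!"role" %in% names(table)) table <- classify_roles(table)
  d <- dplyr::slice_min(table, .data$rank, n = top_n)
  ggplot(d, aes(x = .data$integrated_centrality,
                y = stats::reorder(.data$food, -.data$rank),
                fill = .data$role)) +
    ggplot2::geom_col() +
    labs(x = "Integrated centrality (mean of 5 z-scores)", y = NULL,
         fill = "network role") +
    theme_minimal()
}
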