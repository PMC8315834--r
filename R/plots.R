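#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_line labs theme_minimal facet_wrap position_dodge
#' @export
ggplot2::autoplot

#' Plot per-target precision and recall
#'
#' Scatter of per-target precision versus recall with dashed contours of
#' constant F1; point size encodes the target support.
#'
#' @param object An `mnb_score`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mnb_score <- function(object, ...) {
  contours <- purrr::map_dfr(c(0.2, 0.4, 0.6, 0.8), function(f1) {
    p <- seq(f1 / (2 - f1) + 1e-4, 1, length.out = 100)
    r <- f1 * p / (2 * p - f1)
    tibble::tibble(f1 = factor(f1), precision = p, recall = r)
  })
  ggplot(object$per_target, aes(x = .data$recall, y = .data$precision)) +
    geom_line(data = contours,
              aes(group = .data$f1), linetype = "dashed",
              colour = "grey70", linewidth = 0.3) +
    geom_point(aes(size = .data$support), alpha = 0.6, colour = "#046C9A") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "recall", y = "precision", size = "support",
         title = sprintf("Support-weighted total F1 = %.3f", object$total_f1)) +
    theme_minimal()
}

#' Plot the generalized disease network
#'
#' Fruchterman-Reingold layout (seeded) of the giant component with nodes
#' coloured by Louvain cluster.
#'
#' @param object A `disease_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disease_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes[match(igraph::V(g)$name, object$nodes$feature), ]
  nodes <- dplyr::mutate(nodes, x = xy[, 1], y = xy[, 2])
  e <- igraph::as_data_frame(g, what = "edges")
  ei <- match(e$from, nodes$feature)
  ej <- match(e$to, nodes$feature)
  edges <- tibble::tibble(x = nodes$x[ei], y = nodes$y[ei],
                          xend = nodes$x[ej], yend = nodes$y[ej])
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = edges,
                 aes(xend = .data$xend, yend = .data$yend),
                 colour = "grey80", linewidth = 0.2) +
    geom_point(aes(colour = factor(.data$cluster)), size = 2) +
    labs(colour = "cluster", x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot cohort-comparison rates
#'
#' Grouped bars of prevalence/incidence per group, faceted by diagnosis
#' block and sex.
#'
#' @param object A `cohort_comparison`.
#' @param measure `"prevalence"` or `"incidence"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, measure = "prevalence", ...) {
  long <- object$rates |>
    dplyr::filter(.data$measure == !!measure) |>
    dplyr::select("block", "sex", "rate_control", "rate_anchor",
                  "rate_larger") |>
    tidyr::pivot_longer(dplyr::starts_with("rate_"), names_to = "group",
                        names_prefix = "rate_", values_to = "rate")
  long$group <- factor(long$group, levels = c("control", "anchor", "larger"))
  ggplot(long, aes(x = .data$group, y = .data$rate, fill = .data$sex)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~block) +
    labs(y = measure, x = NULL) +
    theme_minimal()
}
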