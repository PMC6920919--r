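#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot per-sample diversity by season
#'
#' Box-and-point panels of richness, Shannon, Simpson (1-D) and Pielou
#' evenness for leaf samples, split by season.
#'
#' @param profile Output of [diversity_profile()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(profile) {
  leaf <- profile[profile$source == "leaf", ]
  long <- tidyr::pivot_longer(
    leaf[, c("sample_id", "season", "richness", "shannon", "simpson", "pielou")],
    cols = c("richness", "shannon", "simpson", "pielou"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$season, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Alpha diversity by season")
}

#' Plot the habitat-occupancy histogram
#'
#' Bars of OTU counts by number of habitats occupied, filled by air
#' presence (occupancy zero = air-only OTUs).
#'
#' @param occ Output of [occupancy()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ) {
  hist <- occupancy_histogram(occ)
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$n_habitats_occupied),
                                     y = .data$n_otus,
                                     fill = .data$present_in_air)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Habitats occupied", y = "OTUs",
                  fill = "Also in air",
                  title = "OTU habitat occupancy")
}

#' Plot the Levins niche-breadth distribution
#'
#' Histogram of B_j with the specialist and generalist thresholds marked.
#'
#' @param niche Output of [levins_index()].
#' @param specialist_threshold,generalist_threshold Thresholds to mark
#'   (defaults 5 and 10).
#' @return A ggplot object.
#' @export
plot_niche_breadth <- function(niche, specialist_threshold = 5,
                               generalist_threshold = 10) {
  ggplot2::ggplot(niche, ggplot2::aes(x = .data$breadth)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = c(specialist_threshold, generalist_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "Levins niche breadth B", y = "OTUs",
                  title = "Niche breadth distribution")
}

#' Plot a UPGMA dendrogram
#'
#' Base-graphics dendrogram with the cut level(s) marked as horizontal
#' similarity lines.
#'
#' @param x A `phn_dendrogram`.
#' @param cut_similarities Similarity levels (percent) to mark.
#' @param ... Passed to `plot.hclust`.
#' @return `x`, invisibly.
#' @export
plot.phn_dendrogram <- function(x, cut_similarities = NULL, ...) {
  plot(x$hclust, hang = -1, xlab = "", sub = "",
       ylab = "Bray-Curtis dissimilarity", ...)
  if (!is.null(cut_similarities)) {
    graphics::abline(h = 1 - cut_similarities / 100, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Autoplot a co-occurrence network
#'
#' Simple force-layout rendering of a `phn_network`, nodes coloured by
#' taxon label when present.
#'
#' @param object A `phn_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phn_network <- function(object, ...) {
  g <- object$graph
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(
    name = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2],
    taxon = if (!is.null(igraph::V(g)$taxon)) igraph::V(g)$taxon else "OTU"
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$taxon), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, title = "MIC co-occurrence network")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
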