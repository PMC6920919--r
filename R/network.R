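#' Build a MIC co-occurrence network
#'
#' Computes the MIC between every pair of OTU abundance vectors over the
#' chosen samples and draws an undirected edge wherever the score exceeds
#' `mic_threshold` (strictly) and the Spearman rank correlation is
#' positive — MIC measures strength but is sign-blind, so positivity of the
#' association is enforced through the rank correlation. Isolated nodes are
#' dropped by default.
#'
#' @param x An [otu_table()].
#' @param otus Optional character vector restricting the node set (e.g. a
#'   SIMPER discriminating set). Default: all OTUs with nonzero reads in
#'   the chosen samples.
#' @param samples Optional character vector of sample ids (e.g. the members
#'   of one cluster). Default: all samples.
#' @param mic_threshold Edge threshold on the MIC score (default 0.5).
#' @param min_samples Minimum number of samples required (default 5): MIC
#'   on fewer points is degenerate. Lower it only deliberately.
#' @param drop_isolated Drop nodes with no edges (default `TRUE`).
#' @param alpha,c,method Passed to [mic()].
#' @return A list of class `phn_network`: `graph` (igraph object, node
#'   attribute `taxon` when taxonomy is present), `edges` tibble
#'   (`otu_a`, `otu_b`, `mic`, `rho`), and the parameters used.
#' @export
build_network <- function(x, otus = NULL, samples = NULL,
                          mic_threshold = 0.5, min_samples = 5,
                          drop_isolated = TRUE,
                          alpha = 0.6, c = 15, method = "exact") {
  stopifnot(inherits(x, "otu_table"))
  samples <- samples %||% colnames(x$counts)
  if (length(samples) < min_samples) {
    stop(sprintf("network construction needs at least %d samples, got %d",
                 min_samples, length(samples)))
  }
  sub <- x$counts[, samples, drop = FALSE]
  otus <- otus %||% rownames(sub)[rowSums(sub) > 0]
  otus <- intersect(otus, rownames(sub))
  if (length(otus) < 2) stop("need at least 2 OTUs")
  sub <- sub[otus, , drop = FALSE]

  pairs <- utils::combn(length(otus), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xi <- sub[i, ]; yj <- sub[j, ]
    score <- if (stats::sd(xi) == 0 || stats::sd(yj) == 0) 0 else {
      mic(xi, yj, alpha = alpha, c = c, method = method)
    }
    rho <- suppressWarnings(stats::cor(xi, yj, method = "spearman"))
    tibble(otu_a = otus[i], otu_b = otus[j],
           mic = score, rho = ifelse(is.na(rho), 0, rho))
  })
  edges <- res[res$mic > mic_threshold & res$rho > 0, ]

  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b")], directed = FALSE,
    vertices = data.frame(name = otus)
  )
  igraph::E(g)$mic <- edges$mic
  igraph::E(g)$rho <- edges$rho
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  if (!is.null(x$taxonomy)) {
    tax_col <- intersect(c("class", "phylum"), names(x$taxonomy))[1]
    if (!is.na(tax_col)) {
      idx <- match(igraph::V(g)$name, x$taxonomy$otu_id)
      igraph::V(g)$taxon <- as.character(x$taxonomy[[tax_col]][idx])
    }
  }
  structure(
    list(graph = g, edges = edges, all_scores = res,
         mic_threshold = mic_threshold, samples = samples, method = method),
    class = "phn_network"
  )
}

#' @export
print.phn_network <- function(x, ...) {
  cat(sprintf("<phn_network> %d nodes, %d edges (MIC > %.2f over %d samples)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$mic_threshold, length(x$samples)))
  invisible(x)
}

#' @rdname build_network
#' @param ... Unused.
#' @export
tidy.phn_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.phn_network <- function(x, ...) topology(x)

#' Wrap a bare igraph object as a phn_network
#'
#' Mainly for feeding random graphs into [topology()].
#'
#' @param g An igraph object.
#' @return A `phn_network`.
#' @export
as_phn_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  structure(list(graph = g, edges = NULL, mic_threshold = NA_real_,
                 samples = NULL, method = NA_character_),
            class = "phn_network")
}

#' Topological parameters of a network
#'
#' The twelve Cytoscape-style descriptors: node and edge counts, clustering
#' coefficient (mean local transitivity, degree-<2 nodes contributing 0),
#' connected components, diameter and radius (max/min eccentricity within
#' the largest component), degree centralization
#' (N/(N-2)) (k_max/(N-1) - density), number of shortest paths (ordered
#' reachable pairs), characteristic path length (mean geodesic over those
#' pairs), average neighbor count 2E/N, density 2E/(N(N-1)), and degree
#' heterogeneity sd(k)/mean(k) (population sd).
#'
#' @param net A `phn_network` (or igraph object).
#' @param digits Decimal places for the continuous metrics (default 3,
#'   `NA` to leave unrounded).
#' @return A one-row tibble of the twelve parameters. Centralization is
#'   `NA` for graphs with fewer than 3 nodes.
#' @export
topology <- function(net, digits = 3) {
  g <- if (inherits(net, "phn_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  N <- igraph::vcount(g)
  if (N < 1) stop("network has no nodes")
  E <- igraph::ecount(g)
  deg <- igraph::degree(g)

  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- if (N > 0) mean(cc_local) else NA_real_
  comps <- igraph::components(g)

  # eccentricities within the largest component
  main_v <- which(comps$membership == which.max(comps$csize))
  sub <- igraph::induced_subgraph(g, main_v)
  if (igraph::vcount(sub) > 1) {
    ecc <- igraph::eccentricity(sub)
    diam <- max(ecc); rad <- min(ecc)
  } else {
    diam <- 0; rad <- 0
  }

  dmat <- igraph::distances(g)
  finite_off <- is.finite(dmat) & upper.tri(dmat)
  n_paths <- 2L * sum(finite_off)          # ordered reachable pairs
  cpl <- if (n_paths > 0) mean(dmat[finite_off]) else NA_real_

  density <- if (N > 1) 2 * E / (N * (N - 1)) else NA_real_
  centralization <- if (N >= 3) {
    (N / (N - 2)) * (max(deg) / (N - 1) - density)
  } else NA_real_
  mean_k <- mean(deg)
  heterogeneity <- if (mean_k > 0) {
    sqrt(mean((deg - mean_k)^2)) / mean_k
  } else NA_real_

  rnd <- function(v) if (is.na(digits)) v else round(v, digits)
  tibble(
    nodes = N,
    edges = E,
    clustering_coefficient = rnd(clustering),
    connected_components = comps$no,
    diameter = diam,
    radius = rad,
    centralization = rnd(centralization),
    shortest_paths = n_paths,
    characteristic_path_length = rnd(cpl),
    avg_neighbors = rnd(2 * E / N),
    density = rnd(density),
    heterogeneity = rnd(heterogeneity)
  )
}

#' Uniform G(n, m) random graph
#'
#' A simple undirected graph drawn uniformly among graphs with exactly
#' `n_nodes` nodes and `n_edges` edges — the basic null model used to
#' judge whether an observed co-occurrence network is denser or more
#' clustered than chance.
#'
#' @param n_nodes,n_edges Node and edge counts; `n_edges` must not exceed
#'   `choose(n_nodes, 2)`.
#' @param seed Integer seed.
#' @return A `phn_network` wrapping the random graph.
#' @export
random_network <- function(n_nodes, n_edges, seed = 0) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible edge count for a simple graph")
  }
  g <- withr::with_seed(seed, igraph::sample_gnm(n_nodes, n_edges))
  as_phn_network(g)
}

#' Degree-preserving rewired null
#'
#' Alternative null model: the observed graph with edges rewired while
#' preserving every node's degree.
#'
#' @param net A `phn_network`.
#' @param seed Integer seed.
#' @param n_rewires Rewiring attempts (default 100 x edges).
#' @return A `phn_network`.
#' @export
rewired_network <- function(net, seed = 0, n_rewires = NULL) {
  g <- if (inherits(net, "phn_network")) net$graph else net
  n_rewires <- n_rewires %||% (100 * igraph::ecount(g))
  g2 <- withr::with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(niter = n_rewires)))
  as_phn_network(g2)
}

#' Replicate-mode random-network topology
#'
#' Draws `n_rep` G(n, m) graphs and summarises each topological parameter
#' as mean and standard deviation.
#'
#' @inheritParams random_network
#' @param n_rep Number of replicate draws (default 100).
#' @return A tibble: `parameter`, `mean`, `sd`.
#' @export
random_network_summary <- function(n_nodes, n_edges, n_rep = 100, seed = 0) {
  reps <- purrr::map_dfr(seq_len(n_rep), function(i) {
    topology(random_network(n_nodes, n_edges, seed = child_seed(seed, i)),
             digits = NA)
  })
  tidyr::pivot_longer(reps, dplyr::everything(),
                      names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' Export a network to GraphML
#'
#' @param net A `phn_network`.
#' @param path Destination file.
#' @return `net`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- if (inherits(net, "phn_network")) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}
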