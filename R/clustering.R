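#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum_k |x_k - y_k| / sum_k (x_k + y_k) over OTU counts, the
#' standard abundance-based community dissimilarity.
#'
#' @param x An [otu_table()] with at least two samples.
#' @return A symmetric matrix of class `matrix` over sample ids, entries in
#'   \[0, 1\], zero diagonal.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (ncol(x$counts) < 2) stop("need at least 2 samples")
  if (any(colSums(x$counts) == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(x$counts)[colSums(x$counts) == 0], collapse = ", "))
  }
  d <- vegan::vegdist(t(x$counts), method = "bray")
  as.matrix(d)
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with group-average linkage on a dissimilarity
#' matrix. Ties in agglomeration are broken towards the pair containing the
#' lexicographically smallest sample label (samples are sorted before
#' clustering, making the resolution deterministic and order-invariant).
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [bray_curtis()]).
#' @return An object of class `phn_dendrogram` wrapping the `hclust` merge
#'   tree; heights are dissimilarities.
#' @export
upgma_cluster <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d))) stop("d must be a symmetric matrix")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.unsorted(hc$height)) {
    stop("non-monotone merge heights under group-average linkage")
  }
  structure(list(hclust = hc, labels = hc$labels), class = "phn_dendrogram")
}

#' @export
print.phn_dendrogram <- function(x, ...) {
  cat(sprintf("<phn_dendrogram> UPGMA tree over %d samples, merge heights %.3f-%.3f\n",
              length(x$labels), min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Convert a dendrogram to Newick
#'
#' @param tree A `phn_dendrogram`.
#' @param path Optional file path; when given the Newick string is written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phn_dendrogram"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut a dendrogram at a similarity level
#'
#' Groups samples connected by merges strictly below height 1 - s/100,
#' i.e. at more than s% Bray-Curtis similarity. Cluster labels are letters
#' (`A`, `B`, ...) ordered by each cluster's first sample label.
#'
#' @param tree A `phn_dendrogram` from [upgma_cluster()].
#' @param similarity_percent Cut level as percent similarity in (0, 100).
#' @return A tibble: `sample_id`, `cluster`, with the cut level stored in
#'   attribute `"similarity_percent"`.
#' @export
cut_clusters <- function(tree, similarity_percent) {
  stopifnot(inherits(tree, "phn_dendrogram"))
  if (similarity_percent <= 0 || similarity_percent >= 100) {
    stop("similarity_percent must be in (0, 100)")
  }
  h_cut <- 1 - similarity_percent / 100
  hc <- tree$hclust
  n <- length(hc$labels)
  # union-find over merges strictly below the cut height
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[m, ], function(v) {
      if (v < 0) -v else node_members[[v]]
    }))
    node_members[[m]] <- members
    if (hc$height[m] < h_cut) {
      r <- find(members[1])
      for (i in members[-1]) parent[find(i)] <- r
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  labs <- hc$labels
  first_member <- vapply(split(labs, comp), min, character(1))
  comp_order <- names(sort(first_member))
  cluster <- LETTERS[match(as.character(comp), comp_order)]
  out <- tibble(sample_id = labs, cluster = cluster)
  out <- out[order(out$cluster, out$sample_id), ]
  attr(out, "similarity_percent") <- similarity_percent
  out
}

# pairwise Clarke decomposition: per-OTU contribution (percent scale) to the
# similarity of one sample pair; contributions sum to 100 * (1 - bray)
pair_similarity_contributions <- function(xk, yk) {
  denom <- sum(xk + yk)
  if (denom == 0) stop("pair of all-zero samples")
  100 * 2 * pmin(xk, yk) / denom
}

#' SIMPER: within-cluster similarity decomposition
#'
#' For every within-cluster sample pair the Bray-Curtis similarity
#' S = 100 (1 - d) is decomposed into additive per-OTU contributions
#' 100 * 2 min(x_k, y_k) / sum_m (x_m + y_m); the per-OTU contribution to a
#' cluster is the mean over its pairs and the contributions sum exactly to
#' the cluster's average within-group similarity. The discriminating set of
#' a cluster collects OTUs in decreasing contribution order until their
#' cumulative share of the total reaches `cumulative_cutoff`.
#'
#' @param x An [otu_table()].
#' @param clusters Tibble from [cut_clusters()] (columns `sample_id`,
#'   `cluster`), or any data frame mapping samples to cluster labels.
#' @param cumulative_cutoff Cumulative contribution fraction defining the
#'   discriminating set (default 0.9).
#' @return A list of class `phn_simper`: `clusters` tibble
#'   (`cluster`, `n_samples`, `average_similarity`) and `contributions`
#'   tibble (`cluster`, `otu_id`, `contribution`, `percent`,
#'   `cumulative_percent`, `discriminating`). Singleton clusters are
#'   skipped with a warning.
#' @export
simper <- function(x, clusters, cumulative_cutoff = 0.9) {
  stopifnot(inherits(x, "otu_table"))
  cl <- split(clusters$sample_id, clusters$cluster)
  res_cl <- list()
  res_ct <- list()
  for (lab in names(cl)) {
    ids <- cl[[lab]]
    if (length(ids) < 2) {
      warning(sprintf("cluster '%s' has a single sample; skipped", lab))
      next
    }
    sub <- x$counts[, ids, drop = FALSE]
    pairs <- utils::combn(length(ids), 2)
    contrib <- matrix(0, nrow(sub), ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      contrib[, p] <- pair_similarity_contributions(sub[, pairs[1, p]],
                                                    sub[, pairs[2, p]])
    }
    mean_contrib <- rowMeans(contrib)
    avg_sim <- sum(mean_contrib)
    ord <- order(mean_contrib, decreasing = TRUE)
    pct <- 100 * mean_contrib[ord] / avg_sim
    cum <- cumsum(pct)
    disc <- cum <= 100 * cumulative_cutoff
    # always include the OTU that crosses the cutoff
    if (any(!disc)) disc[which(!disc)[1]] <- TRUE
    res_cl[[lab]] <- tibble(cluster = lab, n_samples = length(ids),
                            average_similarity = avg_sim)
    res_ct[[lab]] <- tibble(
      cluster = lab,
      otu_id = rownames(sub)[ord],
      contribution = mean_contrib[ord],
      percent = pct,
      cumulative_percent = cum,
      discriminating = disc & mean_contrib[ord] > 0
    )
  }
  structure(
    list(clusters = dplyr::bind_rows(res_cl),
         contributions = dplyr::bind_rows(res_ct),
         cumulative_cutoff = cumulative_cutoff),
    class = "phn_simper"
  )
}

#' @export
print.phn_simper <- function(x, ...) {
  cat("<phn_simper> within-cluster similarity decomposition\n")
  print(x$clusters)
  invisible(x)
}

#' @rdname simper
#' @param ... Unused.
#' @export
tidy.phn_simper <- function(x, ...) x$contributions

#' @rdname simper
#' @export
glance.phn_simper <- function(x, ...) x$clusters

#' Discriminating OTUs unique to one cluster
#'
#' OTUs in a cluster's discriminating (cumulative-cutoff) set and in no
#' other cluster's: an interpretation of taxa "solely responsible" for a
#' cluster's formation.
#'
#' @param sim A `phn_simper` result.
#' @return A tibble: `cluster`, `otu_id`.
#' @export
simper_sole_discriminants <- function(sim) {
  disc <- sim$contributions[sim$contributions$discriminating, c("cluster", "otu_id")]
  dplyr::group_by(disc, .data$otu_id) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster, .data$otu_id)
}

#' SIMPER: between-cluster dissimilarity decomposition
#'
#' For every pair of samples taken across two clusters the Bray-Curtis
#' dissimilarity (percent scale) is decomposed into per-OTU contributions
#' 100 |x_k - y_k| / sum_m (x_m + y_m), averaged over pairs.
#'
#' @param x An [otu_table()].
#' @param clusters Cluster assignment tibble as for [simper()].
#' @return A list of class `phn_simper_between`: `pairs` tibble
#'   (`cluster_a`, `cluster_b`, `average_dissimilarity`) and
#'   `contributions` tibble (`cluster_a`, `cluster_b`, `otu_id`,
#'   `contribution`, `percent`, `cumulative_percent`).
#' @export
simper_between <- function(x, clusters) {
  stopifnot(inherits(x, "otu_table"))
  cl <- split(clusters$sample_id, clusters$cluster)
  if (length(cl) < 2) stop("need at least two clusters")
  labs <- names(cl)
  res_p <- list()
  res_c <- list()
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (b <= a) next
      ids_a <- cl[[labs[a]]]
      ids_b <- cl[[labs[b]]]
      contrib <- matrix(0, nrow(x$counts), length(ids_a) * length(ids_b))
      p <- 0
      for (i in ids_a) for (j in ids_b) {
        p <- p + 1
        xi <- x$counts[, i]
        yj <- x$counts[, j]
        contrib[, p] <- 100 * abs(xi - yj) / sum(xi + yj)
      }
      mean_contrib <- rowMeans(contrib)
      avg_dis <- sum(mean_contrib)
      ord <- order(mean_contrib, decreasing = TRUE)
      pct <- 100 * mean_contrib[ord] / avg_dis
      key <- paste(labs[a], labs[b], sep = "|")
      res_p[[key]] <- tibble(cluster_a = labs[a], cluster_b = labs[b],
                             average_dissimilarity = avg_dis)
      res_c[[key]] <- tibble(
        cluster_a = labs[a], cluster_b = labs[b],
        otu_id = rownames(x$counts)[ord],
        contribution = mean_contrib[ord],
        percent = pct,
        cumulative_percent = cumsum(pct)
      )
    }
  }
  structure(
    list(pairs = dplyr::bind_rows(res_p),
         contributions = dplyr::bind_rows(res_c)),
    class = "phn_simper_between"
  )
}
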