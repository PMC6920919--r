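#' Convert airborne gene copies per volume to copies per gram of air
#'
#' Air density at sea level is roughly 1/800 that of water, i.e. 1250 g per
#' cubic metre, so copies per gram = copies per m^3 / 1250. The result is
#' reported to 3 significant figures.
#'
#' @param copies_per_m3 Gene copies per cubic metre of air.
#' @param air_density_g_per_m3 Air density in g m^-3 (default 1250).
#' @param signif_digits Significant figures (default 3; `NA` to skip
#'   rounding).
#' @return Copies per gram of air.
#' @export
air_copies_per_gram <- function(copies_per_m3, air_density_g_per_m3 = 1250,
                                signif_digits = 3) {
  if (any(copies_per_m3 < 0)) stop("copies_per_m3 must be non-negative")
  if (any(air_density_g_per_m3 <= 0)) stop("air density must be positive")
  out <- copies_per_m3 / air_density_g_per_m3
  if (!is.na(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis: input paths (or a simulate
#' block), rarefaction depth and seed, abundance and Levins thresholds,
#' cluster cut levels, SIMPER cutoff, MIC threshold and parameters, and the
#' null-model replicate count.
#'
#' @param table_path,metadata_path,taxonomy_path Input TSV paths; leave
#'   `NULL` to simulate instead.
#' @param simulate A [synthetic_config()] used when no input paths are
#'   given.
#' @param depth Rarefaction depth (`NULL` = minimum sample total).
#' @param rarefaction_seed Seed for the rarefaction draw.
#' @param abundant_threshold,rare_threshold Overall abundance class cutoffs.
#' @param specialist_threshold,generalist_threshold Levins cutoffs.
#' @param cut_similarities Cluster cut levels, percent similarity.
#' @param simper_cutoff Cumulative SIMPER contribution cutoff.
#' @param mic_threshold,mic_alpha,mic_c,mic_method MIC settings.
#' @param min_network_samples Minimum samples for network construction.
#' @param null_replicates,null_seed G(n,m) null draws per network and seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL,
                            simulate = synthetic_config(),
                            depth = NULL, rarefaction_seed = 0,
                            abundant_threshold = 0.01, rare_threshold = 0.001,
                            specialist_threshold = 5, generalist_threshold = 10,
                            cut_similarities = c(20, 35),
                            simper_cutoff = 0.9,
                            mic_threshold = 0.5, mic_alpha = 0.6, mic_c = 15,
                            mic_method = "exact",
                            min_network_samples = 5,
                            null_replicates = 100, null_seed = 0) {
  cfg <- as.list(environment())
  stopifnot(
    abundant_threshold > rare_threshold,
    specialist_threshold < generalist_threshold,
    all(cut_similarities > 0 & cut_similarities < 100),
    simper_cutoff > 0 && simper_cutoff <= 1,
    mic_threshold >= 0 && mic_threshold <= 1
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full community-structure pipeline
#'
#' Executes, in order: read (or simulate) the OTU table; singleton removal;
#' rarefaction; chloroplast/unclassified exclusion; per-sample diversity
#' with paired seasonal comparisons; abundance, occupancy and Levins
#' classification with the summary table; Bray-Curtis UPGMA clustering with
#' cuts and SIMPER; MIC networks per cluster (clusters large enough) with
#' topology and G(n,m) null summaries. When `out_dir` is given every stage
#' writes its TSV/JSON/Newick/GraphML outputs there, plus a run manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `phn_pipeline` with elements `table`,
#'   `diversity`, `seasonal`, `abundance`, `occupancy`, `niche`, `summary`,
#'   `dissimilarity`, `tree`, `clusters`, `simper`, `networks`,
#'   `topology`, `nulls`, `truth` (synthetic runs only) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("phyllonet")),
                   timestamp = NA, config = config[setdiff(names(config), "simulate")])

  truth <- NULL
  if (!is.null(config$table_path)) {
    message("stage read: ", config$table_path)
    tab <- read_otu_table(config$table_path, config$metadata_path,
                          config$taxonomy_path)
  } else {
    message("stage simulate: seed ", config$simulate$seed)
    sim <- generate_community(config$simulate)
    tab <- sim$table
    truth <- sim$truth
    manifest$simulate_seed <- config$simulate$seed
  }
  n0 <- nrow(tab$counts)

  tab <- remove_singletons(tab)
  message(sprintf("stage singletons: %d -> %d OTUs", n0, nrow(tab$counts)))

  tab <- rarefy(tab, depth = config$depth, seed = config$rarefaction_seed)
  message(sprintf("stage rarefy: depth %d, %d OTUs retained",
                  tab$provenance$depth, nrow(tab$counts)))

  if (!is.null(tab$taxonomy)) {
    n1 <- nrow(tab$counts)
    tab <- remove_excluded_taxa(tab)
    message(sprintf("stage taxon filter: %d -> %d OTUs", n1, nrow(tab$counts)))
  }

  div <- diversity_profile(tab)
  seas <- seasonal_diversity_comparison(div)
  abund <- classify_abundance(tab, config$abundant_threshold, config$rare_threshold)
  occ <- occupancy(tab)
  niche <- levins_index(tab, config$specialist_threshold, config$generalist_threshold)
  summ <- classification_summary(tab, abund, occ, niche)

  d <- bray_curtis(tab)
  tree <- upgma_cluster(d)
  cuts <- purrr::map(config$cut_similarities, ~ cut_clusters(tree, .x))
  names(cuts) <- paste0("s", config$cut_similarities)
  main_cut <- cuts[[1]]
  sim_res <- simper(tab, main_cut, config$simper_cutoff)

  networks <- list()
  topo <- list()
  nulls <- list()
  for (lab in unique(main_cut$cluster)) {
    ids <- main_cut$sample_id[main_cut$cluster == lab]
    if (length(ids) < config$min_network_samples) {
      message(sprintf("stage network: cluster %s has %d samples (< %d); skipped",
                      lab, length(ids), config$min_network_samples))
      next
    }
    disc <- sim_res$contributions
    disc <- disc$otu_id[disc$cluster == lab & disc$discriminating]
    net <- build_network(tab, otus = disc, samples = ids,
                         mic_threshold = config$mic_threshold,
                         min_samples = config$min_network_samples,
                         alpha = config$mic_alpha, c = config$mic_c,
                         method = config$mic_method)
    networks[[lab]] <- net
    tp <- if (igraph::vcount(net$graph) == 0) {
      # nothing passed the MIC threshold: report the empty network honestly
      tibble(nodes = 0L, edges = 0L, clustering_coefficient = NA_real_,
             connected_components = 0L, diameter = NA_real_, radius = NA_real_,
             centralization = NA_real_, shortest_paths = 0L,
             characteristic_path_length = NA_real_, avg_neighbors = NA_real_,
             density = NA_real_, heterogeneity = NA_real_)
    } else {
      topology(net)
    }
    topo[[lab]] <- dplyr::mutate(tp, cluster = lab, .before = 1)
    if (tp$edges > 0) {
      nulls[[lab]] <- dplyr::mutate(
        random_network_summary(tp$nodes, tp$edges,
                               n_rep = config$null_replicates,
                               seed = config$null_seed),
        cluster = lab, .before = 1)
    }
    message(sprintf("stage network: cluster %s -> %d nodes, %d edges",
                    lab, tp$nodes, tp$edges))
  }

  out <- structure(
    list(table = tab, diversity = div, seasonal = seas, abundance = abund,
         occupancy = occ, niche = niche, summary = summ,
         dissimilarity = d, tree = tree, clusters = cuts,
         simper = sim_res,
         networks = networks,
         topology = dplyr::bind_rows(topo),
         nulls = dplyr::bind_rows(nulls),
         truth = truth, manifest = manifest),
    class = "phn_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config)
  out
}

write_pipeline_outputs <- function(res, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_otu_table(res$table, p("otu_table.tsv"), p("metadata.tsv"),
                  p("taxonomy.tsv"), p("provenance.json"))
  readr::write_tsv(res$diversity, p("diversity.tsv"))
  readr::write_tsv(res$seasonal, p("seasonal_comparison.tsv"))
  readr::write_tsv(res$abundance$overall, p("abundance_classes.tsv"))
  readr::write_tsv(res$occupancy, p("occupancy.tsv"))
  readr::write_tsv(occupancy_histogram(res$occupancy), p("occupancy_histogram.tsv"))
  readr::write_tsv(res$niche, p("levins.tsv"))
  readr::write_tsv(res$summary, p("classification_summary.tsv"))
  readr::write_tsv(as_tibble(as.data.frame(res$dissimilarity), rownames = "sample_id"),
                   p("bray_curtis.tsv"))
  dendrogram_newick(res$tree, p("dendrogram.nwk"))
  for (nm in names(res$clusters)) {
    readr::write_tsv(res$clusters[[nm]], p(paste0("clusters_", nm, ".tsv")))
  }
  readr::write_tsv(res$simper$contributions, p("simper_contributions.tsv"))
  readr::write_tsv(res$simper$clusters, p("simper_clusters.tsv"))
  for (lab in names(res$networks)) {
    readr::write_tsv(res$networks[[lab]]$edges, p(paste0("network_", lab, "_edges.tsv")))
    write_network_graphml(res$networks[[lab]], p(paste0("network_", lab, ".graphml")))
  }
  if (nrow(res$topology) > 0) readr::write_tsv(res$topology, p("topology.tsv"))
  if (!is.null(res$nulls) && nrow(res$nulls) > 0) {
    readr::write_tsv(res$nulls, p("topology_nulls.tsv"))
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

#' Re-derive reported cells from their inputs
#'
#' Consistency audit over a pipeline result: every sample column of the
#' rarefied table sums to the declared depth; the summary-table percentage
#' cells recompute from their counts and denominators; the density and
#' average-neighbour cells of every topology row recompute from the node
#' and edge counts; SIMPER per-OTU contributions sum back to each cluster's
#' average within-group similarity.
#'
#' @param res A `phn_pipeline` result.
#' @param tol Numeric tolerance for the algebraic identities.
#' @return `TRUE` invisibly; a failed check raises an error naming the cell.
#' @export
pipeline_consistency_check <- function(res, tol = 1e-9) {
  stopifnot(inherits(res, "phn_pipeline"))
  depth <- res$table$provenance$depth
  if (!is.null(depth) && any(colSums(res$table$counts) != depth)) {
    stop("a rarefied sample does not sum to the declared depth")
  }
  s <- res$summary
  total <- s$count[s$type == "OTUs in the dataset"]
  n_leaf <- s$count[s$type == "OTUs in the phyllosphere"]
  n_air <- s$count[s$type == "OTUs in the air"]
  for (i in seq_len(nrow(s))) {
    if (!is.na(s$overall_pct[i]) &&
        s$overall_pct[i] != summary_percent(s$count[i], total)) {
      stop("summary overall percentage does not recompute: ", s$type[i])
    }
    if (!is.na(s$within_group_pct[i])) {
      denom <- if (identical(s$within_group[i], "air")) n_air else n_leaf
      if (s$within_group_pct[i] != summary_percent(s$count[i], denom)) {
        stop("summary within-group percentage does not recompute: ", s$type[i])
      }
    }
  }
  tp <- res$topology[res$topology$nodes > 1, , drop = FALSE]
  if (nrow(tp) > 0) {
    if (any(abs(tp$density - round(2 * tp$edges / (tp$nodes * (tp$nodes - 1)), 3)) > tol) ||
        any(abs(tp$avg_neighbors - round(2 * tp$edges / tp$nodes, 3)) > tol)) {
      stop("topology density/avg_neighbors do not recompute from N and E")
    }
  }
  agg <- res$simper$contributions |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(total = sum(.data$contribution), .groups = "drop")
  cmp <- dplyr::left_join(agg, res$simper$clusters, by = "cluster")
  if (any(abs(cmp$total - cmp$average_similarity) > 1e-6)) {
    stop("SIMPER contributions do not sum to the average within-group similarity")
  }
  invisible(TRUE)
}
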