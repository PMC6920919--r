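#' Abundant / rare classification
#'
#' Classifies every OTU by overall relative abundance (fraction of all reads
#' in the dataset): abundant when > `abundant_threshold`, rare when <
#' `rare_threshold`, intermediate otherwise. Inequalities are strict: an
#' OTU sitting exactly on a threshold is intermediate. Local (within-sample)
#' categories use the same thresholds on per-sample fractions.
#'
#' @param x An [otu_table()], normally rarefied.
#' @param abundant_threshold Overall fraction above which an OTU is abundant
#'   (default 0.01).
#' @param rare_threshold Overall fraction below which an OTU is rare
#'   (default 0.001).
#' @return A list with `overall`: tibble (`otu_id`, `fraction`, `category`)
#'   and `local`: tibble (`otu_id`, `sample_id`, `fraction`, `category`,
#'   zero-count cells omitted).
#' @export
classify_abundance <- function(x, abundant_threshold = 0.01,
                               rare_threshold = 0.001) {
  stopifnot(inherits(x, "otu_table"))
  if (nrow(x$counts) == 0 || sum(x$counts) == 0) stop("empty table")
  cat_of <- function(f) {
    dplyr::case_when(
      f > abundant_threshold ~ "abundant",
      f < rare_threshold ~ "rare",
      TRUE ~ "intermediate"
    )
  }
  frac <- rowSums(x$counts) / sum(x$counts)
  overall <- tibble(otu_id = rownames(x$counts), fraction = unname(frac),
                    category = cat_of(unname(frac)))
  local_frac <- sweep(x$counts, 2, colSums(x$counts), "/")
  nz <- which(x$counts > 0, arr.ind = TRUE)
  local <- tibble(
    otu_id = rownames(x$counts)[nz[, 1]],
    sample_id = colnames(x$counts)[nz[, 2]],
    fraction = local_frac[nz],
    category = paste0("locally_", cat_of(local_frac[nz]))
  )
  list(overall = overall, local = local)
}

#' Habitat occupancy
#'
#' Counts, per OTU, the number of plant-species habitats in which it is
#' detected (at least one read in either season on that species; seasons
#' pooled) and whether it is also detected in the air.
#'
#' @param x An [otu_table()] whose metadata identifies habitats and air.
#' @return A tibble: `otu_id`, `n_habitats_occupied`, `present_in_air`,
#'   `universal` (occupies every habitat), `single_habitat`.
#' @export
occupancy <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  md <- x$metadata
  habitats <- unique(md$habitat[md$source == "leaf"])
  present_h <- vapply(habitats, function(h) {
    cols <- md$sample_id[md$habitat == h]
    rowSums(x$counts[, cols, drop = FALSE]) > 0
  }, logical(nrow(x$counts)))
  air_cols <- md$sample_id[md$source == "air"]
  in_air <- if (length(air_cols) > 0) {
    rowSums(x$counts[, air_cols, drop = FALSE]) > 0
  } else {
    rep(FALSE, nrow(x$counts))
  }
  n_occ <- as.integer(rowSums(present_h))
  tibble(
    otu_id = rownames(x$counts),
    n_habitats_occupied = n_occ,
    present_in_air = unname(in_air),
    universal = n_occ == length(habitats),
    single_habitat = n_occ == 1L
  )
}

#' Occupancy histogram
#'
#' Tallies OTUs by number of habitats occupied, split by air presence
#' (including the occupancy-zero, air-only bar).
#'
#' @param occ Output of [occupancy()].
#' @return A tibble: `n_habitats_occupied`, `present_in_air`, `n_otus`.
#' @export
occupancy_histogram <- function(occ) {
  dplyr::count(occ, .data$n_habitats_occupied, .data$present_in_air,
               name = "n_otus")
}

#' Levins niche breadth and generalist/specialist classification
#'
#' For each OTU j, p_ij is the share of the OTU's reads found in sample i
#' (so the p_ij sum to 1 over samples) and the niche breadth is
#' B_j = 1 / sum_i p_ij^2. B_j ranges from 1 (all reads in one sample) to N,
#' the number of samples (perfectly uniform spread). OTUs with B_j above
#' `generalist_threshold` are generalists, below `specialist_threshold`
#' specialists, otherwise intermediate (strict inequalities).
#'
#' On a table rarefied to equal depth this row-share normalisation is
#' identical to normalising by relative abundances; with unequal sample
#' depths a warning is raised and row shares are used regardless.
#'
#' @param x An [otu_table()].
#' @param specialist_threshold,generalist_threshold Classification cutoffs
#'   (defaults 5 and 10).
#' @param leaf_only If `TRUE`, air samples are excluded before computing
#'   p_ij (so N counts leaf samples only). Default `FALSE`: all samples.
#' @return A tibble: `otu_id`, `breadth` (B_j), `n_samples` (N),
#'   `category`.
#' @export
levins_index <- function(x, specialist_threshold = 5,
                         generalist_threshold = 10, leaf_only = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (leaf_only) {
    keep <- x$metadata$sample_id[x$metadata$source == "leaf"]
    counts <- counts[, keep, drop = FALSE]
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("every OTU must have total reads > 0")
  if (length(unique(colSums(counts))) > 1) {
    warning("unequal sample depths; proportions computed on row shares regardless")
  }
  p <- counts / totals
  B <- 1 / rowSums(p^2)
  tibble(
    otu_id = rownames(counts),
    breadth = unname(B),
    n_samples = ncol(counts),
    category = dplyr::case_when(
      B > generalist_threshold ~ "generalist",
      B < specialist_threshold ~ "specialist",
      TRUE ~ "intermediate"
    )
  )
}

#' Summary classification table
#'
#' Assembles the dataset-level counts of OTU classes (phyllosphere/air,
#' abundant/rare, generalist/specialist, per-season, universal and
#' single-habitat) with their percentage contributions: overall percentages
#' against the total OTU count, within-group percentages against the
#' phyllosphere or air OTU count as appropriate. Percentages are rounded
#' half-away-from-zero to integers.
#'
#' @param x The rarefied [otu_table()] the classifications were computed on.
#' @param abundance Output of [classify_abundance()] (computed if `NULL`).
#' @param occ Output of [occupancy()] (computed if `NULL`).
#' @param niche Output of [levins_index()] (computed if `NULL`).
#' @return A tibble: `type`, `count`, `overall_pct`, `within_group_pct`
#'   (`NA` where the paper's table leaves the cell empty), `within_group`
#'   (`"phyllosphere"`, `"air"` or `NA`).
#' @export
classification_summary <- function(x, abundance = NULL, occ = NULL, niche = NULL) {
  stopifnot(inherits(x, "otu_table"))
  abundance <- abundance %||% classify_abundance(x)
  occ <- occ %||% occupancy(x)
  niche <- niche %||% levins_index(x)
  md <- x$metadata

  leaf_cols <- md$sample_id[md$source == "leaf"]
  air_cols <- md$sample_id[md$source == "air"]
  season_cols <- function(src, ssn) md$sample_id[md$source == src & md$season == ssn]
  present_in <- function(cols) {
    if (length(cols) == 0) rep(FALSE, nrow(x$counts))
    else rowSums(x$counts[, cols, drop = FALSE]) > 0
  }

  in_leaf <- present_in(leaf_cols)
  in_air <- present_in(air_cols)
  total <- nrow(x$counts)
  n_leaf <- sum(in_leaf)
  n_air <- sum(in_air)

  abundant <- abundance$overall$category == "abundant"
  rare <- abundance$overall$category == "rare"

  row_def <- list(
    list("OTUs in the dataset", total, NA, NA_character_),
    list("OTUs in the phyllosphere", n_leaf, NA, NA_character_),
    list("OTUs in the air", n_air, NA, NA_character_),
    list("Abundant OTUs", sum(abundant), NA, NA_character_),
    list("Rare OTUs", sum(rare), NA, NA_character_),
    list("Generalist OTUs (Levins)", sum(niche$category == "generalist"), NA, NA_character_),
    list("Specialist OTUs (Levins)", sum(niche$category == "specialist"), NA, NA_character_),
    list("OTUs on leaves in summer", sum(present_in(season_cols("leaf", "summer"))), n_leaf, "phyllosphere"),
    list("OTUs on leaves in winter", sum(present_in(season_cols("leaf", "winter"))), n_leaf, "phyllosphere"),
    list("OTUs in the air in summer", sum(present_in(season_cols("air", "summer"))), n_air, "air"),
    list("OTUs in the air in winter", sum(present_in(season_cols("air", "winter"))), n_air, "air"),
    list("Abundant OTUs on leaves", sum(abundant & in_leaf), n_leaf, "phyllosphere"),
    list("Rare OTUs on leaves", sum(rare & in_leaf), n_leaf, "phyllosphere"),
    list("Universal OTUs", sum(occ$universal), n_leaf, "phyllosphere"),
    list("OTUs on only one habitat", sum(occ$single_habitat), n_leaf, "phyllosphere")
  )
  purrr::map_dfr(row_def, function(r) {
    tibble(
      type = r[[1]],
      count = as.integer(r[[2]]),
      overall_pct = if (r[[1]] == "OTUs in the dataset") NA_integer_ else
        as.integer(round_half_up(100 * r[[2]] / total)),
      within_group_pct = if (is.na(r[[3]]) || length(r[[3]]) == 0) NA_integer_ else
        as.integer(round_half_up(100 * r[[2]] / r[[3]])),
      within_group = r[[4]]
    )
  })
}

#' Percentage-cell arithmetic for summary tables
#'
#' The rounding rule used throughout the summary table: integer percentage
#' of `count` against `denominator`, half away from zero.
#'
#' @param count Numerator count.
#' @param denominator Denominator count.
#' @return Integer percentage.
#' @export
summary_percent <- function(count, denominator) {
  as.integer(round_half_up(100 * count / denominator))
}
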