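#' Per-sample alpha diversity
#'
#' Richness, Shannon diversity (natural log), Simpson diversity (1-D) and
#' Pielou's evenness for every sample. Pielou's J = H / ln(S) is undefined
#' (reported `NA`) for single-OTU samples.
#'
#' @param x An [otu_table()].
#' @param base Logarithm base for Shannon H and the evenness denominator
#'   (default `exp(1)`, natural log).
#' @return A tibble with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `simpson` (1-D), `pielou`, joined with the sample metadata.
#' @export
diversity_profile <- function(x, base = exp(1)) {
  stopifnot(inherits(x, "otu_table"))
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("all-zero sample: ", colnames(x$counts)[which(totals == 0)[1]])
  }
  comm <- t(x$counts)  # vegan convention: rows = samples
  S <- rowSums(comm > 0)
  H <- vegan::diversity(comm, index = "shannon", base = base)
  D1 <- vegan::diversity(comm, index = "simpson")
  J <- ifelse(S > 1, H / (log(S) / log(base)), NA_real_)
  out <- tibble(
    sample_id = colnames(x$counts),
    richness = as.integer(S),
    shannon = as.numeric(H),
    simpson = as.numeric(D1),
    pielou = as.numeric(J)
  )
  dplyr::left_join(out, x$metadata, by = "sample_id")
}

#' Paired summer/winter comparison
#'
#' Two-sided paired t-test of summer against winter values matched by
#' habitat. When one season is identically zero across all pairs the test
#' degrades to a one-sample t-test of the other season against zero. A
#' zero-variance difference vector is reported as an exact tie (`t` and `p`
#' are `NA`, `tie` is `TRUE`).
#'
#' @param values A data frame with columns `habitat`, `season` and `value`
#'   (one value per habitat x season), or columns `summer` and `winter`
#'   (one row per habitat).
#' @param attribute Label for the compared quantity (stored in the output).
#' @return A one-row tibble: `attribute`, `summer_mean`, `summer_se`,
#'   `winter_mean`, `winter_se`, `df`, `t`, `p`, `tie`, `method`.
#' @export
paired_season_test <- function(values, attribute = "value") {
  if (all(c("summer", "winter") %in% names(values))) {
    wide <- as_tibble(values)
  } else {
    stopifnot(all(c("habitat", "season", "value") %in% names(values)))
    wide <- tidyr::pivot_wider(
      as_tibble(values)[, c("habitat", "season", "value")],
      names_from = "season", values_from = "value"
    )
    if (!all(c("summer", "winter") %in% names(wide))) {
      stop("values must contain both seasons for each habitat")
    }
  }
  su <- wide$summer
  wi <- wide$winter
  n <- length(su)
  if (n < 2) stop("need at least 2 habitat pairs")
  se <- function(v) stats::sd(v) / sqrt(length(v))

  base_row <- tibble(
    attribute = attribute,
    summer_mean = mean(su), summer_se = se(su),
    winter_mean = mean(wi), winter_se = se(wi),
    df = n - 1L
  )
  if (all(wi == 0) && !all(su == 0)) {
    # one season identically zero: one-sample test of the other against 0
    tt <- stats::t.test(su, mu = 0)
    method <- "one-sample vs 0 (winter all zero)"
  } else if (all(su == 0) && !all(wi == 0)) {
    tt <- stats::t.test(wi, mu = 0)
    method <- "one-sample vs 0 (summer all zero)"
  } else {
    d <- su - wi
    if (stats::sd(d) == 0) {
      # all differences equal: identical seasons give the exact null
      # (t = 0, p = 1); a nonzero constant shift leaves t undefined
      return(dplyr::mutate(base_row,
        t = if (all(d == 0)) 0 else NA_real_,
        p = if (all(d == 0)) 1 else NA_real_,
        tie = TRUE, method = "paired t (degenerate: zero-variance differences)"
      ))
    }
    tt <- stats::t.test(su, wi, paired = TRUE)
    method <- "paired t"
  }
  dplyr::mutate(base_row,
    t = unname(tt$statistic), p = tt$p.value, tie = FALSE, method = method
  )
}

#' Seasonal comparison table for the standard diversity attributes
#'
#' Runs [paired_season_test()] over richness, Shannon, Simpson and Pielou
#' values of the leaf samples, matched by habitat.
#'
#' @param profile Output of [diversity_profile()].
#' @return A tibble with one row per attribute (Table-1 shaped).
#' @export
seasonal_diversity_comparison <- function(profile) {
  leaf <- profile[profile$source == "leaf", ]
  attrs <- c("richness", "shannon", "simpson", "pielou")
  purrr::map_dfr(attrs, function(a) {
    vals <- tibble(habitat = leaf$habitat, season = leaf$season,
                   value = leaf[[a]])
    paired_season_test(vals, attribute = a)
  })
}

#' Seasonal comparison per taxonomic group
#'
#' Sums reads per taxonomic group (a taxonomy column, typically `phylum` or
#' `class`) within each leaf sample, then compares seasons pairwise by
#' habitat; groups with one season identically zero fall back to the
#' one-sample test.
#'
#' @param x An [otu_table()] with taxonomy.
#' @param rank Taxonomy column to aggregate by (default `"phylum"`).
#' @return A tibble with one row per group (Table-3 shaped).
#' @export
seasonal_taxon_comparison <- function(x, rank = "phylum") {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$taxonomy)) stop("taxonomy required")
  long <- tidy.otu_table(x)
  long <- dplyr::left_join(long, x$taxonomy[, c("otu_id", rank)], by = "otu_id")
  leaf <- long[long$source == "leaf", ]
  leaf$group <- leaf[[rank]]
  sums <- leaf |>
    dplyr::group_by(.data$group, .data$habitat, .data$season) |>
    dplyr::summarise(value = sum(.data$count), .groups = "drop")
  groups <- sort(unique(sums$group))
  purrr::map_dfr(groups, function(g) {
    paired_season_test(sums[sums$group == g, ], attribute = g)
  })
}
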