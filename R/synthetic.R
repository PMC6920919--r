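#' Configuration for the synthetic community generator
#'
#' Defines the study design the generator emulates: nine plant-species
#' habitats sampled in summer and winter plus one air sample per season,
#' every sample carrying the same fixed read depth, lognormally distributed
#' OTU base abundances, a small block of universal generalists holding the
#' top abundance ranks, a large majority of single-habitat specialists whose
#' seasonal activity produces summer-enriched richness, a band of
#' intermediate-breadth OTUs occupying 4-5 habitats, and species-poor air
#' samples assembled by thinning the pooled leaf community plus an air-only
#' OTU block.
#'
#' @param n_habitats Number of plant-species habitats (default 9).
#' @param n_air_samples_per_season Air samples per season (default 1).
#' @param depth Reads per sample (default 5038).
#' @param n_otus Total OTUs planted (default 890).
#' @param lognormal_mu,lognormal_sigma Parameters of the lognormal base
#'   abundance distribution (defaults 0 and 2: a few dominant and many very
#'   rare OTUs).
#' @param frac_generalists Fraction of OTUs planted as universal generalists
#'   (default 0.011, i.e. 10 of 890).
#' @param frac_single_habitat Fraction planted as single-habitat specialists
#'   (default 0.885, i.e. 788 of 890).
#' @param n_air_only Number of OTUs present only in the air (default 21).
#' @param summer_richness_factor Ratio of specialist summer presence to
#'   winter presence, >= 1 (default 1.6).
#' @param winter_activity Probability that a specialist is active in winter
#'   (default 0.55); summer activity is `min(1, winter_activity *
#'   summer_richness_factor)`.
#' @param background_habitats Candidate habitat counts for
#'   intermediate-breadth OTUs (default `c(3, 4)`: with both seasons and
#'   possible presence in the two air samples their expected Levins breadth
#'   spans 6-10, inside the intermediate band by construction).
#' @param air_thinning Probability that a leaf OTU is also airborne
#'   (default 0.25); controls air-sample species poverty.
#' @param air_only_weight Expected fraction of the air community held by
#'   the air-only block (default 0.5); the remainder is the thinned pooled
#'   leaf community. Makes air samples compositionally distinct from
#'   leaves, as the study's air cluster is.
#' @param sample_noise_sd Standard deviation (log scale) of multiplicative
#'   per-OTU-per-sample abundance heterogeneity (default 0.3). Mild enough
#'   that every planted role's expected niche breadth stays inside its
#'   classification band (the effective-sample-count factor is
#'   exp(-sd^2) = 0.91).
#' @param summer_association_sd Standard deviation (log scale) of a shared
#'   per-summer-sample factor applied to the generalist block (default 0 =
#'   off). When positive it plants a dense block of positive co-occurrence
#'   across summer samples, used for network null-model contrasts.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_habitats = 9,
                             n_air_samples_per_season = 1,
                             depth = 5038,
                             n_otus = 890,
                             lognormal_mu = 0,
                             lognormal_sigma = 2,
                             frac_generalists = 0.011,
                             frac_single_habitat = 0.885,
                             n_air_only = 21,
                             summer_richness_factor = 1.6,
                             winter_activity = 0.55,
                             background_habitats = c(3, 4),
                             air_thinning = 0.25,
                             air_only_weight = 0.5,
                             sample_noise_sd = 0.3,
                             summer_association_sd = 0,
                             seed = 0) {
  cfg <- as.list(environment())
  if (frac_generalists + frac_single_habitat > 1) {
    stop("frac_generalists + frac_single_habitat must be <= 1")
  }
  if (summer_richness_factor < 1) stop("summer_richness_factor must be >= 1")
  if (depth <= 0) stop("depth must be positive")
  if (winter_activity * (1 + summer_richness_factor) < 1) {
    stop("winter_activity too low: no feasible seasonal presence split")
  }
  n_roles <- sum(round(n_otus * c(frac_generalists, frac_single_habitat))) +
    n_air_only
  if (n_roles > n_otus) stop("role fractions and n_air_only exceed n_otus")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic phyllosphere/air community
#'
#' Draws one OTU table under the design described in [synthetic_config()].
#' Per-sample counts are a single multinomial draw of `depth` reads from
#' sample-specific expected relative abundances (lognormal base abundances
#' x habitat-occupancy mask x seasonal activity); the
#' `"compose_rarefy"` mode instead over-samples each sample threefold and
#' rarefies back down with [rarefy()], exercising the rarefaction path.
#'
#' @param config A [synthetic_config()].
#' @param sampling `"multinomial"` (default, one draw at depth) or
#'   `"compose_rarefy"`.
#' @return A list with elements `table` (an [otu_table()] with metadata and
#'   a light synthetic taxonomy; all-zero OTUs dropped), `truth` (tibble of
#'   planted per-OTU roles: `otu_id`, `role`, `home_habitat`, `habitats`
#'   (list-column), `airborne`, `active_summer`, `active_winter`,
#'   `seasonal_bias`, `base_abundance`), `expected` (matrix of expected
#'   relative abundances per sample, including the drawn per-sample
#'   heterogeneity) and `expected_structural` (the design expectation
#'   before heterogeneity, for noise-free limit checks).
#' @export
generate_community <- function(config = synthetic_config(),
                               sampling = c("multinomial", "compose_rarefy")) {
  stopifnot(inherits(config, "synthetic_config"))
  sampling <- match.arg(sampling)
  withr::with_seed(config$seed, generate_community_impl(config, sampling))
}

generate_community_impl <- function(cfg, sampling) {
  n_gen <- round(cfg$n_otus * cfg$frac_generalists)
  n_spec <- round(cfg$n_otus * cfg$frac_single_habitat)
  n_air_only <- cfg$n_air_only
  n_bg <- cfg$n_otus - n_gen - n_spec - n_air_only
  habitats <- paste0("H", seq_len(cfg$n_habitats))

  otu_ids <- sprintf("OTU%04d", seq_len(cfg$n_otus))
  base <- stats::rlnorm(cfg$n_otus, cfg$lognormal_mu, cfg$lognormal_sigma)
  base <- sort(base, decreasing = TRUE)
  # generalists are the community's dominant, ubiquitous members: they take
  # the top abundance ranks; all remaining ranks are assigned to roles at
  # random
  role <- rep(NA_character_, cfg$n_otus)
  role[seq_len(n_gen)] <- "generalist"
  rest <- sample((n_gen + 1):cfg$n_otus)
  role[rest[seq_len(n_spec)]] <- "specialist"
  role[rest[n_spec + seq_len(n_air_only)]] <- "air_only"
  role[is.na(role)] <- "background"

  # seasonal presence split for specialists: winter presence w, summer
  # presence s = min(1, w * f); P(both) = s + w - 1
  w <- cfg$winter_activity
  s <- min(1, w * cfg$summer_richness_factor)
  p_both <- s + w - 1
  p_summer_only <- 1 - w
  p_winter_only <- 1 - s

  active_summer <- rep(TRUE, cfg$n_otus)
  active_winter <- rep(TRUE, cfg$n_otus)
  is_spec <- role == "specialist"
  profile <- sample(c("both", "summer_only", "winter_only"), sum(is_spec),
                    replace = TRUE, prob = c(p_both, p_summer_only, p_winter_only))
  active_summer[is_spec] <- profile != "winter_only"
  active_winter[is_spec] <- profile != "summer_only"

  home <- rep(NA_character_, cfg$n_otus)
  home[is_spec] <- sample(habitats, sum(is_spec), replace = TRUE)
  habitat_sets <- vector("list", cfg$n_otus)
  for (i in seq_len(cfg$n_otus)) {
    habitat_sets[[i]] <- switch(role[i],
      generalist = habitats,
      specialist = home[i],
      background = sample(habitats, sample(cfg$background_habitats, 1)),
      air_only = character(0)
    )
  }
  airborne <- stats::runif(cfg$n_otus) < cfg$air_thinning
  airborne[role == "generalist"] <- TRUE
  airborne[role == "air_only"] <- TRUE

  occ <- matrix(FALSE, cfg$n_otus, cfg$n_habitats, dimnames = list(otu_ids, habitats))
  for (i in seq_len(cfg$n_otus)) occ[i, habitat_sets[[i]]] <- TRUE

  meta <- dplyr::bind_rows(
    tidyr::expand_grid(habitat = habitats, season = c("summer", "winter")) |>
      dplyr::mutate(sample_id = paste0(.data$habitat, "_", .data$season),
                    source = "leaf"),
    tidyr::expand_grid(season = c("summer", "winter"),
                       rep = seq_len(cfg$n_air_samples_per_season)) |>
      dplyr::mutate(
        sample_id = if (cfg$n_air_samples_per_season == 1) {
          paste0("air_", .data$season)
        } else {
          paste0("air_", .data$season, "_", .data$rep)
        },
        source = "air", habitat = "air") |>
      dplyr::select(-"rep")
  ) |>
    dplyr::select("sample_id", "source", "habitat", "season")

  # shared summer factor over the generalist block (association planting)
  assoc_block <- which(role == "generalist")
  summer_leaf_ids <- meta$sample_id[meta$source == "leaf" & meta$season == "summer"]
  assoc_factor <- stats::setNames(rep(1, nrow(meta)), meta$sample_id)
  if (cfg$summer_association_sd > 0) {
    assoc_factor[summer_leaf_ids] <-
      stats::rlnorm(length(summer_leaf_ids), 0, cfg$summer_association_sd)
  }

  # per-OTU-per-sample multiplicative heterogeneity, drawn once and part of
  # the dataset's expected proportions
  noise <- matrix(
    stats::rlnorm(cfg$n_otus * nrow(meta), 0, cfg$sample_noise_sd),
    cfg$n_otus, nrow(meta)
  )
  expected <- matrix(0, cfg$n_otus, nrow(meta), dimnames = list(otu_ids, meta$sample_id))
  expected_structural <- expected
  for (j in seq_len(nrow(meta))) {
    sm <- meta[j, ]
    act <- if (sm$season == "summer") active_summer else active_winter
    if (sm$source == "leaf") {
      wgt <- base * occ[, sm$habitat] * act
      if (cfg$summer_association_sd > 0 && sm$season == "summer") {
        wgt[assoc_block] <- wgt[assoc_block] * assoc_factor[sm$sample_id]
      }
    } else {
      # air: mixture of the thinned pooled leaf community (weight prop. to
      # base x habitats occupied) and the air-only block
      pooled <- base * rowSums(occ) * act * airborne
      ao <- base * act * (role == "air_only")
      if (sum(pooled) > 0) pooled <- pooled / sum(pooled)
      if (sum(ao) > 0) ao <- ao / sum(ao)
      wgt <- (1 - cfg$air_only_weight) * pooled + cfg$air_only_weight * ao
    }
    if (sum(wgt) <= 0) {
      stop(sprintf("infeasible config: no OTU eligible for sample '%s'", sm$sample_id))
    }
    expected_structural[, j] <- wgt / sum(wgt)
    wgt <- wgt * noise[, j]
    expected[, j] <- wgt / sum(wgt)
  }

  draw_depth <- if (sampling == "compose_rarefy") 3L * cfg$depth else cfg$depth
  counts <- matrix(0L, cfg$n_otus, nrow(meta), dimnames = dimnames(expected))
  for (j in seq_len(ncol(counts))) {
    counts[, j] <- stats::rmultinom(1, draw_depth, expected[, j])[, 1]
  }

  taxonomy <- synthetic_taxonomy(otu_ids, role)
  truth <- tibble(
    otu_id = otu_ids,
    planted_class = role,
    role = ifelse(.data$planted_class == "air_only", "background",
                  .data$planted_class),
    home_habitat = ifelse(.data$planted_class == "air_only", "air", home),
    habitats = habitat_sets,
    airborne = airborne,
    active_summer = active_summer,
    active_winter = active_winter,
    seasonal_bias = dplyr::case_when(
      active_summer & !active_winter ~ Inf,
      !active_summer & active_winter ~ -Inf,
      TRUE ~ 0
    ),
    base_abundance = base
  )

  keep <- rowSums(counts) > 0
  tab <- otu_table(
    counts[keep, , drop = FALSE], meta,
    taxonomy[taxonomy$otu_id %in% otu_ids[keep], ],
    provenance = list(generator = "phyllonet synthetic community",
                      seed = cfg$seed, depth = cfg$depth, sampling = sampling)
  )
  if (sampling == "compose_rarefy") {
    tab <- rarefy(tab, depth = cfg$depth, seed = cfg$seed)
  }
  list(table = tab, truth = truth, expected = expected,
       expected_structural = expected_structural,
       config = cfg, metadata = meta)
}

# light synthetic lineage labels so taxonomy-consuming steps have something
# to chew on; group frequencies loosely follow a Mediterranean phyllosphere
synthetic_taxonomy <- function(otu_ids, role) {
  groups <- c("Alphaproteobacteria", "Betaproteobacteria", "Gammaproteobacteria",
              "Actinobacteria", "Bacteroidetes", "Firmicutes", "Acidobacteria",
              "Deinococcus", "Other")
  probs <- c(0.32, 0.10, 0.07, 0.22, 0.10, 0.06, 0.05, 0.02, 0.06)
  grp <- sample(groups, length(otu_ids), replace = TRUE, prob = probs)
  grp[role == "generalist"] <- sample(c("Alphaproteobacteria", "Actinobacteria"),
                                      sum(role == "generalist"), replace = TRUE)
  phylum <- dplyr::case_when(
    grepl("proteobacteria$", grp) ~ "Proteobacteria",
    grp == "Other" ~ "Other",
    TRUE ~ grp
  )
  tibble(
    otu_id = otu_ids,
    domain = "Bacteria",
    phylum = phylum,
    class = grp,
    order = NA_character_,
    closest_relative = NA_character_
  )
}

#' Recovery of planted niche roles
#'
#' Scores the Levins generalist/specialist calls computed on a synthetic
#' table against the roles the generator planted. Air-only OTUs carry no
#' phyllosphere niche role and are excluded; planted OTUs never observed in
#' the table cannot be classified and are reported separately rather than
#' counted as misses.
#'
#' @param truth The `truth` tibble from [generate_community()].
#' @param niche The tibble returned by [levins_index()].
#' @param occupancy Optional tibble from [occupancy()]; when given, an
#'   occupancy confusion table (planted vs observed habitat counts) is
#'   included.
#' @return A list of class `phn_recovery`: `roles` (per-class `tp`, `fp`,
#'   `fn`, `precision`, `recall`; `NA` for an empty class),
#'   `n_unobserved` planted-but-unsampled OTUs, and `occupancy` (confusion
#'   tibble or `NULL`).
#' @export
recovery_report <- function(truth, niche, occupancy = NULL) {
  if (!all(niche$otu_id %in% truth$otu_id)) {
    stop("classified OTU ids are not a subset of the planted OTU ids")
  }
  eval_truth <- truth[truth$planted_class != "air_only", ]
  joined <- dplyr::inner_join(
    eval_truth[, c("otu_id", "role")],
    niche[, c("otu_id", "category")],
    by = "otu_id"
  )
  score_class <- function(cls) {
    tp <- sum(joined$role == cls & joined$category == cls)
    fp <- sum(joined$role != cls & joined$category == cls)
    fn <- sum(joined$role == cls & joined$category != cls)
    tibble(
      class = cls, tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
      recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    )
  }
  roles <- dplyr::bind_rows(score_class("generalist"), score_class("specialist"))

  occ_conf <- NULL
  if (!is.null(occupancy)) {
    n_hab <- lengths(eval_truth$habitats)
    names(n_hab) <- eval_truth$otu_id
    occ_joined <- dplyr::inner_join(
      tibble(otu_id = names(n_hab), planted_habitats = as.integer(n_hab)),
      occupancy[, c("otu_id", "n_habitats_occupied")],
      by = "otu_id"
    )
    occ_conf <- dplyr::count(occ_joined, .data$planted_habitats,
                             .data$n_habitats_occupied, name = "n_otus")
  }
  structure(
    list(roles = roles,
         n_unobserved = sum(eval_truth$otu_id %notin% niche$otu_id),
         occupancy = occ_conf),
    class = "phn_recovery"
  )
}

#' @export
print.phn_recovery <- function(x, ...) {
  cat("<phn_recovery> planted-role recovery\n")
  print(x$roles)
  cat(sprintf("%d planted OTUs unobserved in the table\n", x$n_unobserved))
  invisible(x)
}

#' @rdname recovery_report
#' @param x A `phn_recovery` object.
#' @param ... Unused.
#' @export
tidy.phn_recovery <- function(x, ...) x$roles
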