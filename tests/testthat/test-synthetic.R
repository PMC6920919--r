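test_that("generator produces the study design and is deterministic per seed", {
  cfg <- synthetic_config(seed = 5, n_otus = 200)
  sim1 <- generate_community(cfg)
  sim2 <- generate_community(cfg)
  expect_identical(sim1$table$counts, sim2$table$counts)
  expect_identical(sim1$truth, sim2$truth)

  # 9 habitats x 2 seasons + 2 air = 20 samples, every column at depth
  expect_equal(ncol(sim1$table$counts), 20)
  expect_true(all(colSums(sim1$table$counts) == cfg$depth))
  expect_equal(sum(sim1$table$metadata$source == "air"), 2)

  sim3 <- generate_community(synthetic_config(seed = 6, n_otus = 200))
  expect_false(identical(sim1$table$counts, sim3$table$counts))
})

test_that("planted single-habitat OTUs never exceed one observed habitat", {
  for (s in 1:5) {
    sim <- generate_community(synthetic_config(seed = s, n_otus = 300))
    occ <- occupancy(sim$table)
    spec_ids <- sim$truth$otu_id[sim$truth$planted_class == "specialist"]
    expect_lte(max(occ$n_habitats_occupied[occ$otu_id %in% spec_ids]), 1)
    air_ids <- sim$truth$otu_id[sim$truth$planted_class == "air_only"]
    obs_air <- occ[occ$otu_id %in% air_ids, ]
    expect_true(all(obs_air$n_habitats_occupied == 0))
    expect_true(all(obs_air$present_in_air))
  }
})

test_that("empirical proportions converge to expected proportions with depth", {
  cfg_lo <- synthetic_config(seed = 9, n_otus = 150, n_air_only = 4, depth = 1000)
  cfg_hi <- synthetic_config(seed = 9, n_otus = 150, n_air_only = 4, depth = 100000)
  err <- function(cfg) {
    sim <- generate_community(cfg)
    obs <- matrix(0, nrow(sim$expected), ncol(sim$expected),
                  dimnames = dimnames(sim$expected))
    obs[rownames(sim$table$counts), ] <- sim$table$counts
    mean(abs(sweep(obs, 2, colSums(obs), "/") - sim$expected))
  }
  expect_lt(err(cfg_hi), err(cfg_lo) / 3)
})

test_that("classification on the structural expectation recovers roles perfectly", {
  sim <- generate_community(synthetic_config(seed = 2))
  p <- sim$expected_structural
  B <- 1 / rowSums((p / rowSums(p))^2)
  calls <- ifelse(B > 10, "generalist", ifelse(B < 5, "specialist", "intermediate"))
  tr <- sim$truth
  expect_true(all(calls[tr$planted_class == "generalist"] == "generalist"))
  expect_true(all(calls[tr$planted_class == "specialist"] == "specialist"))
  expect_true(all(calls[tr$planted_class == "background"] == "intermediate"))
})

test_that("recovery report scores calls against planted roles", {
  sim <- generate_community(synthetic_config(seed = 4))
  niche <- levins_index(sim$table)
  rec <- recovery_report(sim$truth, niche, occupancy(sim$table))
  expect_s3_class(tidy(rec), "tbl_df")
  r <- rec$roles
  expect_true(all(r$recall >= 0.9, na.rm = TRUE))
  expect_true(all(r$precision >= 0.9, na.rm = TRUE))
  expect_true(!is.null(rec$occupancy))

  # foreign ids are a hard error
  bad <- niche
  bad$otu_id[1] <- "NOT_PLANTED"
  expect_error(recovery_report(sim$truth, bad), "subset")

  # no planted generalists: precision/recall not applicable, not 0
  tr0 <- sim$truth[sim$truth$planted_class != "generalist", ]
  n0 <- niche[niche$otu_id %in% tr0$otu_id & niche$category != "generalist", ]
  rec0 <- recovery_report(tr0, n0)
  expect_true(is.na(rec0$roles$recall[rec0$roles$class == "generalist"]))
})

test_that("summer richness enrichment emerges across seeds", {
  wins <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    sim <- generate_community(synthetic_config(seed = 100 + s, n_otus = 400))
    div <- diversity_profile(sim$table)
    leaf <- div[div$source == "leaf", ]
    if (mean(leaf$richness[leaf$season == "summer"]) >
        mean(leaf$richness[leaf$season == "winter"])) wins <- wins + 1
  }
  expect_gte(wins, n_seeds - 1)
})

test_that("compose-then-rarefy mode lands on the same depth", {
  sim <- generate_community(synthetic_config(seed = 3, n_otus = 150, n_air_only = 4, depth = 800),
                            sampling = "compose_rarefy")
  expect_true(all(colSums(sim$table$counts) == 800))
})

test_that("infeasible configs fail loudly", {
  expect_error(synthetic_config(frac_generalists = 0.5, frac_single_habitat = 0.6),
               "<= 1")
  expect_error(synthetic_config(summer_richness_factor = 0.5), ">= 1")
  expect_error(synthetic_config(winter_activity = 0.2), "feasible")
})
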