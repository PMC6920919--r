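test_that("abundance classes use strict thresholds on dataset-wide fractions", {
  # 10000 reads total: 200 = 2% abundant; exactly 10 = 0.1% intermediate;
  # 5 = 0.05% rare
  m <- matrix(c(200L, 10L, 5L, 9785L), 4, 1,
              dimnames = list(c("big", "edge", "tiny", "rest"), "S1"))
  cls <- classify_abundance(tiny_table(m))
  ov <- cls$overall
  expect_equal(ov$category[ov$otu_id == "big"], "abundant")
  expect_equal(ov$category[ov$otu_id == "edge"], "intermediate")
  expect_equal(ov$category[ov$otu_id == "tiny"], "rare")
  expect_equal(sum(ov$fraction), 1, tolerance = 1e-12)

  # an OTU at exactly 1% is intermediate, and 1000 equal OTUs at 0.1% each
  # yield neither abundant nor rare calls
  m2 <- matrix(rep(10L, 1000), 1000, 1,
               dimnames = list(sprintf("o%04d", 1:1000), "S1"))
  ov2 <- classify_abundance(tiny_table(m2))$overall
  expect_true(all(ov2$category == "intermediate"))

  m3 <- matrix(c(1L, 99L), 2, 1, dimnames = list(c("one", "x"), "S1"))
  ov3 <- classify_abundance(tiny_table(m3))$overall
  expect_equal(ov3$category[ov3$otu_id == "one"], "intermediate")

  expect_error(classify_abundance(tiny_table(
    matrix(integer(0), 0, 1, dimnames = list(character(0), "S1")))), "empty")
})

test_that("occupancy pools seasons and flags air presence", {
  tab <- design_table(n_otu = 4, counts_fun = function(n, m) matrix(0L, n, m))
  tab$counts["OTU001", c("H1_summer", "H1_winter")] <- 5L
  tab$counts["OTU002", paste0("H", 1:9, "_summer")] <- 1L
  tab$counts["OTU003", c("air_summer", "air_winter")] <- 3L
  tab$counts["OTU004", c("H2_winter", "air_summer")] <- 2L
  occ <- occupancy(tab)
  expect_equal(occ$n_habitats_occupied[occ$otu_id == "OTU001"], 1L)
  expect_true(occ$single_habitat[occ$otu_id == "OTU001"])
  expect_true(occ$universal[occ$otu_id == "OTU002"])
  expect_equal(occ$n_habitats_occupied[occ$otu_id == "OTU003"], 0L)
  expect_true(occ$present_in_air[occ$otu_id == "OTU003"])
  expect_true(occ$present_in_air[occ$otu_id == "OTU004"])

  hist <- occupancy_histogram(occ)
  expect_equal(sum(hist$n_otus), 4)
})

test_that("Levins breadth matches its closed forms and thresholds", {
  n <- 15
  m <- matrix(0L, 3, n, dimnames = list(c("uniform", "single", "two"),
                                        paste0("S", 1:n)))
  m["uniform", ] <- 10L
  m["single", 1] <- 30L
  m["two", 1:2] <- c(20L, 20L)
  md <- tiny_metadata(colnames(m))
  tab <- otu_table(m, md)
  nb <- suppressWarnings(levins_index(tab))
  expect_equal(nb$breadth[nb$otu_id == "uniform"], 15, tolerance = 1e-12)
  expect_equal(nb$category[nb$otu_id == "uniform"], "generalist")
  expect_equal(nb$breadth[nb$otu_id == "single"], 1, tolerance = 1e-12)
  expect_equal(nb$breadth[nb$otu_id == "two"], 2, tolerance = 1e-12)
  expect_equal(nb$category[nb$otu_id == "two"], "specialist")
  expect_true(all(nb$breadth >= 1 & nb$breadth <= n))
})

test_that("Levins breadth is scale-invariant and monotone under concentration", {
  withr::with_seed(11, {
    tab <- design_table(n_otu = 20,
                        counts_fun = function(n, m) matrix(rpois(n * m, 8), n, m))
  })
  nb1 <- levins_index(tab)
  tab2 <- tab
  tab2$counts["OTU005", ] <- tab2$counts["OTU005", ] * 7L
  nb2 <- suppressWarnings(levins_index(tab2))
  expect_equal(nb2$breadth[nb2$otu_id == "OTU005"],
               nb1$breadth[nb1$otu_id == "OTU005"], tolerance = 1e-12)

  # moving reads from a low-share sample to the top sample never increases B
  for (otu in c("OTU001", "OTU002", "OTU003")) {
    row <- tab$counts[otu, ]
    lo <- which.min(replace(row, row == 0, NA))
    hi <- which.max(row)
    b_before <- 1 / sum((row / sum(row))^2)
    row2 <- row
    row2[lo] <- row2[lo] - 1L
    row2[hi] <- row2[hi] + 1L
    b_after <- 1 / sum((row2 / sum(row2))^2)
    expect_lte(b_after, b_before + 1e-12)
  }
})

test_that("leaf-only mode restricts the sample universe", {
  sim <- generate_community(synthetic_config(seed = 12, n_otus = 200))
  nb_all <- levins_index(sim$table)
  nb_leaf <- levins_index(sim$table, leaf_only = TRUE)
  expect_equal(unique(nb_all$n_samples), 20)
  expect_equal(unique(nb_leaf$n_samples), 18)
  expect_true(all(nb_leaf$breadth <= 18 + 1e-12))
})

test_that("summary-table arithmetic reproduces its percentage rules", {
  expect_equal(summary_percent(157, 890), 18L)
  expect_equal(summary_percent(381, 869), 44L)
  expect_equal(summary_percent(794, 890), 89L)
  expect_equal(summary_percent(869, 869), 100L)
  # half-away-from-zero, not banker's rounding
  expect_equal(summary_percent(25, 200), 13L)

  sim <- generate_community(synthetic_config(seed = 5, n_otus = 300))
  tab <- sim$table
  s <- classification_summary(tab)
  expect_equal(nrow(s), 15)
  total <- s$count[s$type == "OTUs in the dataset"]
  expect_equal(total, nrow(tab$counts))
  # every percentage cell recomputes from its count and denominator
  n_leaf <- s$count[s$type == "OTUs in the phyllosphere"]
  n_air <- s$count[s$type == "OTUs in the air"]
  for (i in seq_len(nrow(s))) {
    if (!is.na(s$overall_pct[i])) {
      expect_equal(s$overall_pct[i], summary_percent(s$count[i], total))
    }
    if (!is.na(s$within_group_pct[i])) {
      denom <- if (identical(s$within_group[i], "air")) n_air else n_leaf
      expect_equal(s$within_group_pct[i], summary_percent(s$count[i], denom))
    }
  }
})
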