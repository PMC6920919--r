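test_that("Bray-Curtis matches direct evaluation and its bounds", {
  m <- matrix(c(1L, 0L, 2L,
                1L, 1L, 2L,
                0L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("k1", "k2", "k3"), c("X", "Y", "Z")))
  # X = (1,1,0), Y = (0,1,1), Z = (2,2,0) = 2X
  d <- bray_curtis(tiny_table(m))
  expect_equal(d["X", "Y"], 0.5, tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  # scaling both samples by a common factor leaves the index unchanged:
  # d(X, Z) reflects only the doubling mismatch; compare scaled pair instead
  m2 <- cbind(m, X2 = 2L * m[, "X"], Y2 = 2L * m[, "Y"])
  d2 <- bray_curtis(tiny_table(m2))
  expect_equal(d2["X2", "Y2"], d2["X", "Y"], tolerance = 1e-12)

  ident <- matrix(c(3L, 4L, 3L, 4L), 2, 2,
                  dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_equal(bray_curtis(tiny_table(ident))["S1", "S2"], 0)

  disjoint <- matrix(c(3L, 0L, 0L, 4L), 2, 2,
                     dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_equal(bray_curtis(tiny_table(disjoint))["S1", "S2"], 1)

  zero <- matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("S1", "S2")))
  expect_error(bray_curtis(tiny_table(zero)), "S2")
})

test_that("UPGMA reproduces hand-computed merges and the brute-force oracle", {
  # two samples: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_cluster(d2)
  expect_equal(t2$hclust$height, 0.4)

  # three samples, hand-computed group-average: {A,B} at 0.2, +C at 0.6
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_cluster(d3)
  expect_equal(t3$hclust$height, c(0.2, 0.6), tolerance = 1e-12)

  # merge heights match a brute-force group-average oracle on random matrices
  for (trial in 1:30) {
    withr::with_seed(trial, {
      n <- 5
      dm <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
      dm[upper.tri(dm)] <- runif(n * (n - 1) / 2, 0.1, 1)
      dm <- dm + t(dm)
    })
    tree <- upgma_cluster(dm)
    expect_equal(sort(tree$hclust$height), oracle_upgma_heights(dm),
                 tolerance = 1e-10)
  }

  # sample-order invariance up to relabelling
  perm <- c(3, 1, 2)
  dp <- d3[perm, perm]
  tp <- upgma_cluster(dp)
  expect_equal(tp$hclust$height, t3$hclust$height)

  bad <- d3; bad[1, 2] <- 0.9
  expect_error(upgma_cluster(bad), "symmetric")
})

test_that("similarity cuts group by strict merge-height threshold", {
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma_cluster(d3)
  cut50 <- cut_clusters(tree, 50)   # height < 0.5: {A,B}, {C}
  expect_equal(cut50$cluster[cut50$sample_id %in% c("A", "B")], c("A", "A"))
  expect_equal(cut50$cluster[cut50$sample_id == "C"], "B")

  # cut just above the root merges everything; a cut above every merge's
  # similarity isolates all leaves
  expect_equal(unique(cut_clusters(tree, 1)$cluster), "A")
  expect_equal(nrow(dplyr::distinct(cut_clusters(tree, 90), cluster)), 3)

  # newick export round-trips through ape
  nwk <- dendrogram_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})

test_that("SIMPER decomposition matches direct evaluation and conserves totals", {
  # identical pair (50, 50): similarity 100, contributions 50/50
  m <- matrix(c(50L, 50L, 50L, 50L), 2, 2,
              dimnames = list(c("o1", "o2"), c("S1", "S2")))
  cl <- tibble::tibble(sample_id = c("S1", "S2"), cluster = "A")
  sim <- simper(tiny_table(m), cl)
  expect_equal(sim$clusters$average_similarity, 100, tolerance = 1e-12)
  expect_equal(sort(sim$contributions$contribution), c(50, 50), tolerance = 1e-12)

  # x = (4,0,4), y = (0,4,4): similarity 50, contributions (0, 0, 50)
  m2 <- matrix(c(4L, 0L, 0L, 4L, 4L, 4L), 3, 2, byrow = TRUE,
               dimnames = list(c("o1", "o2", "o3"), c("S1", "S2")))
  sim2 <- simper(tiny_table(m2), cl)
  expect_equal(sim2$clusters$average_similarity, 50, tolerance = 1e-12)
  ct <- sim2$contributions
  expect_equal(ct$contribution[ct$otu_id == "o3"], 50, tolerance = 1e-12)
  expect_equal(sum(ct$contribution[ct$otu_id != "o3"]), 0)
  expect_true(all(diff(ct$contribution) <= 1e-12))
  expect_equal(max(ct$cumulative_percent), 100, tolerance = 1e-9)

  # conservation identity on random clusters, against vegan's Bray-Curtis
  for (trial in 1:10) {
    withr::with_seed(trial, {
      mm <- matrix(rpois(30 * 5, 6), 30, 5,
                   dimnames = list(sprintf("o%02d", 1:30), paste0("S", 1:5)))
    })
    tab <- tiny_table(mm)
    cl5 <- tibble::tibble(sample_id = paste0("S", 1:5), cluster = "A")
    s <- simper(tab, cl5)
    expect_equal(sum(s$contributions$contribution),
                 s$clusters$average_similarity, tolerance = 1e-9)
    d <- bray_curtis(tab)
    expect_equal(s$clusters$average_similarity,
                 mean(100 * (1 - d[upper.tri(d)])), tolerance = 1e-9)
  }

  expect_warning(
    simper(tiny_table(m2),
           tibble::tibble(sample_id = c("S1", "S2"), cluster = c("A", "B"))),
    "single sample")
})

test_that("between-group SIMPER agrees with vegan's decomposition", {
  withr::with_seed(5, {
    mm <- matrix(rpois(20 * 6, 7), 20, 6,
                 dimnames = list(sprintf("o%02d", 1:20), paste0("S", 1:6)))
  })
  tab <- tiny_table(mm)
  cl <- tibble::tibble(sample_id = paste0("S", 1:6),
                       cluster = rep(c("A", "B"), each = 3))
  btw <- simper_between(tab, cl)
  ref <- vegan::simper(t(mm), group = cl$cluster)
  ref_avg <- ref$A_B$average  # per-species mean contribution (fraction scale)
  ours <- btw$contributions
  ours <- ours$contribution[match(names(ref_avg), ours$otu_id)]
  expect_equal(ours, unname(100 * ref_avg), tolerance = 1e-9)
  expect_equal(btw$pairs$average_dissimilarity, 100 * sum(ref_avg),
               tolerance = 1e-9)
})

test_that("sole discriminants are unique to one cluster's set", {
  withr::with_seed(9, {
    mm <- matrix(rpois(15 * 6, 5), 15, 6,
                 dimnames = list(sprintf("o%02d", 1:15), paste0("S", 1:6)))
  })
  mm[1, 1:3] <- 80L; mm[1, 4:6] <- 0L   # dominates cluster A only
  tab <- tiny_table(mm)
  cl <- tibble::tibble(sample_id = paste0("S", 1:6),
                       cluster = rep(c("A", "B"), each = 3))
  sole <- simper_sole_discriminants(simper(tab, cl))
  expect_true("o01" %in% sole$otu_id[sole$cluster == "A"])
  expect_false(any(duplicated(sole$otu_id)))
})
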