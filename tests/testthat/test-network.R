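test_that("network construction follows the MIC threshold and sign rule", {
  # five OTUs sharing one abundance profile across 6 samples: complete graph
  prof <- c(1L, 3L, 5L, 7L, 9L, 11L)
  m <- matrix(rep(prof, each = 5), 5, 6,
              dimnames = list(paste0("o", 1:5), paste0("S", 1:6)))
  tab <- tiny_table(m)
  net <- build_network(tab)
  expect_equal(igraph::vcount(net$graph), 5)
  expect_equal(igraph::ecount(net$graph), choose(5, 2))

  # an exclusive threshold of 1 removes every edge
  net1 <- build_network(tab, mic_threshold = 1)
  expect_equal(igraph::ecount(net1$graph), 0)
  expect_equal(igraph::vcount(net1$graph), 0)   # isolated nodes dropped

  # anti-correlated profiles fail the positive-association rule
  m2 <- rbind(up = prof, down = rev(prof))
  storage.mode(m2) <- "integer"
  colnames(m2) <- paste0("S", 1:6)
  net2 <- build_network(tiny_table(m2), drop_isolated = FALSE)
  expect_equal(igraph::ecount(net2$graph), 0)
  expect_true(all(net2$all_scores$mic == 1))

  expect_error(build_network(tab, samples = paste0("S", 1:4)), "at least 5")
})

test_that("planted associations give denser networks than independent noise", {
  dens <- function(assoc, seed) {
    withr::with_seed(seed, {
      n_s <- 18
      shared <- rlnorm(n_s, 0, 1)
      m <- t(vapply(1:12, function(i) {
        lam <- if (assoc) 40 * shared else rlnorm(n_s, log(40), 1)
        rpois(n_s, lam)
      }, numeric(n_s)))
      storage.mode(m) <- "integer"
      dimnames(m) <- list(paste0("o", 1:12), paste0("S", 1:n_s))
    })
    net <- build_network(tiny_table(m), drop_isolated = FALSE)
    igraph::ecount(net$graph) / choose(12, 2)
  }
  wins <- sum(vapply(1:8, function(s) dens(TRUE, s) > dens(FALSE, s),
                     logical(1)))
  expect_gte(wins, 7)
})

test_that("topology reproduces complete-graph identities and the BFS oracle", {
  k4 <- as_phn_network(igraph::make_full_graph(4))
  tp <- topology(k4)
  expect_equal(tp$density, 1)
  expect_equal(tp$clustering_coefficient, 1)
  expect_equal(tp$diameter, 1)
  expect_equal(tp$radius, 1)
  expect_equal(tp$heterogeneity, 0)
  expect_equal(tp$shortest_paths, 12)
  expect_equal(tp$characteristic_path_length, 1)
  expect_equal(tp$centralization, 0)

  # shortest-path metrics agree with a hand-rolled BFS on random graphs
  for (trial in 1:30) {
    g <- withr::with_seed(trial, igraph::sample_gnp(8, 0.35))
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    ref <- oracle_shortest_paths(adj)
    tp <- topology(as_phn_network(g), digits = NA)
    reach <- is.finite(ref) & row(ref) != col(ref)
    expect_equal(tp$shortest_paths, sum(reach))
    if (sum(reach) > 0) {
      expect_equal(tp$characteristic_path_length, mean(ref[reach]),
                   tolerance = 1e-12)
    }
    comp <- igraph::components(g)
    main <- which(comp$membership == which.max(comp$csize))
    if (length(main) > 1) {
      ecc <- apply(ref[main, main, drop = FALSE], 1, max)
      expect_equal(tp$diameter, max(ecc))
      expect_equal(tp$radius, min(ecc))
      expect_lte(tp$radius, tp$diameter)
      expect_lte(tp$diameter, 2 * tp$radius)
    }
    deg <- rowSums(adj)
    expect_equal(tp$avg_neighbors, mean(deg), tolerance = 1e-12)
    if (mean(deg) > 0) {
      expect_equal(tp$heterogeneity, sqrt(mean((deg - mean(deg))^2)) / mean(deg),
                   tolerance = 1e-12)
    }
  }

  # centralization follows the degree formula
  star <- as_phn_network(igraph::make_star(5, mode = "undirected"))
  tps <- topology(star, digits = NA)
  expect_equal(tps$centralization, (5 / 3) * (4 / 4 - 2 * 4 / (5 * 4)),
               tolerance = 1e-12)
})

test_that("G(n,m) nulls have the forced counts and handshake identity", {
  k3 <- random_network(3, 3, seed = 1)
  expect_equal(topology(k3)$density, 1)

  e0 <- random_network(6, 0, seed = 2)
  tp0 <- topology(e0)
  expect_equal(tp0$edges, 0)
  expect_equal(tp0$connected_components, 6)

  for (s in 1:10) {
    g <- random_network(12, 20, seed = s)$graph
    expect_equal(igraph::ecount(g), 20)
    expect_equal(sum(igraph::degree(g)), 40)
    expect_false(igraph::any_multiple(g) || any(igraph::which_loop(g)))
  }
  expect_error(random_network(4, 7), "infeasible")

  rs <- random_network_summary(10, 15, n_rep = 10, seed = 3)
  expect_true(all(c("parameter", "mean", "sd") %in% names(rs)))
  expect_equal(rs$mean[rs$parameter == "edges"], 15)
  expect_equal(rs$sd[rs$parameter == "density"], 0)

  # degree-preserving rewiring keeps the degree sequence
  g <- random_network(10, 14, seed = 4)
  rw <- rewired_network(g, seed = 5)
  expect_equal(sort(igraph::degree(rw$graph)), sort(igraph::degree(g$graph)))
})

test_that("network accessors expose tidy edges and graphml export", {
  prof <- c(1L, 3L, 5L, 7L, 9L, 11L)
  m <- matrix(rep(prof, each = 4), 4, 6,
              dimnames = list(paste0("o", 1:4), paste0("S", 1:6)))
  net <- build_network(tiny_table(m))
  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(nrow(tidy(net)), choose(4, 2))
  expect_equal(glance(net)$nodes, 4)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
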