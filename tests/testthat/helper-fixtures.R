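# small in-code fixtures shared across test files

tiny_metadata <- function(sample_ids, source = "leaf",
                          habitat = NULL, season = "summer") {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    source = rep_len(source, n),
    habitat = if (is.null(habitat)) {
      ifelse(rep_len(source, n) == "air", "air", paste0("P", seq_len(n)))
    } else rep_len(habitat, n),
    season = rep_len(season, n)
  )
}

tiny_table <- function(counts, source = "leaf", habitat = NULL,
                       season = "summer", taxonomy = NULL) {
  otu_table(counts, tiny_metadata(colnames(counts), source, habitat, season),
            taxonomy = taxonomy)
}

# 9 habitats x 2 seasons + 2 air, arbitrary counts, for design-shaped tests
design_table <- function(counts_fun = function(n_otu, n_samp) {
                           matrix(rpois(n_otu * n_samp, 5), n_otu, n_samp)
                         },
                         n_otu = 12, seed = 1) {
  habitats <- paste0("H", 1:9)
  md <- dplyr::bind_rows(
    tidyr::expand_grid(habitat = habitats, season = c("summer", "winter")) |>
      dplyr::mutate(sample_id = paste0(habitat, "_", season), source = "leaf"),
    tibble::tibble(sample_id = c("air_summer", "air_winter"), source = "air",
                   habitat = "air", season = c("summer", "winter"))
  )
  withr::with_seed(seed, {
    m <- counts_fun(n_otu, nrow(md))
    dimnames(m) <- list(sprintf("OTU%03d", seq_len(n_otu)), md$sample_id)
    otu_table(m, md)
  })
}

# independent textbook paired t-test on differences (oracle)
oracle_paired_t <- function(su, wi) {
  d <- su - wi
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1))
}

# brute-force UPGMA (oracle): repeatedly merge the closest pair, group-average
# update weighted by cluster sizes
oracle_upgma_heights <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  active <- seq_along(labs)
  dm <- d
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (j <= i) next
      h <- dm[active[i], active[j]]
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, bh)
    # group-average update against every other active cluster
    for (k in setdiff(active, c(i, j))) {
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active <- setdiff(active, j)
  }
  sort(heights)
}

# brute-force all-pairs shortest paths by repeated BFS (oracle)
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    depth <- 0
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] > 0)) {
          if (!seen[u]) { seen[u] <- TRUE; dist[s, u] <- depth; nxt <- c(nxt, u) }
        }
      }
      frontier <- nxt
    }
  }
  dist
}
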