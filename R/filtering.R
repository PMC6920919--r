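#' Remove singleton OTUs
#'
#' Drops OTUs with a single read in the entire dataset (total reads < 2
#' across all samples), the usual guard against sequencing-error OTUs.
#' Applied to the raw table, before rarefaction.
#'
#' @param x An [otu_table()].
#' @return A filtered [otu_table()]; the ids removed are recorded in
#'   `provenance$singletons_removed`.
#' @export
remove_singletons <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  totals <- rowSums(x$counts)
  keep <- totals >= 2
  removed <- rownames(x$counts)[!keep]
  if (sum(keep) == 0) {
    warning("all OTUs are singletons; result is an empty table")
  }
  out <- subset_otu_table(x, otus = rownames(x$counts)[keep])
  out$provenance$singletons_removed <- length(removed)
  out$provenance$singleton_ids <- removed
  out
}

#' Remove chloroplast and domain-unclassified OTUs
#'
#' Drops OTUs whose taxonomy matches chloroplast-derived or
#' domain-unclassified labels, applied after normalization. Matching is
#' case-insensitive substring search over the lineage columns.
#'
#' @param x An [otu_table()] with taxonomy.
#' @param exclude_labels Character vector of labels to match in any lineage
#'   column (default `"chloroplast"`).
#' @param unclassified_labels Labels that mark a domain-level unclassified
#'   OTU when found in the `domain` column (default `"unclassified"` and
#'   `"unknown"`).
#' @return A filtered [otu_table()]. With no taxonomy attached the table is
#'   returned unchanged with a warning.
#' @export
remove_excluded_taxa <- function(x,
                                 exclude_labels = "chloroplast",
                                 unclassified_labels = c("unclassified", "unknown")) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$taxonomy)) {
    warning("no taxonomy attached; remove_excluded_taxa is a no-op")
    return(x)
  }
  tax <- x$taxonomy
  lineage_cols <- setdiff(names(tax), "otu_id")
  flag_excluded <- rep(FALSE, nrow(tax))
  for (col in lineage_cols) {
    vals <- tolower(as.character(tax[[col]]))
    for (lab in tolower(exclude_labels)) {
      flag_excluded <- flag_excluded | grepl(lab, vals, fixed = TRUE)
    }
  }
  if ("domain" %in% names(tax)) {
    dom <- tolower(as.character(tax$domain))
    for (lab in tolower(unclassified_labels)) {
      flag_excluded <- flag_excluded | grepl(lab, dom, fixed = TRUE)
    }
  }
  drop_ids <- tax$otu_id[flag_excluded]
  keep <- setdiff(rownames(x$counts), drop_ids)
  out <- subset_otu_table(x, otus = keep)
  out$provenance$excluded_taxa_removed <-
    sum(rownames(x$counts) %in% drop_ids)
  out
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples every sample's reads without replacement to exactly `depth`
#' reads (a single draw per seed). OTUs left with zero reads everywhere are
#' dropped. Deterministic for a fixed seed.
#'
#' @param x An [otu_table()].
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Integer seed for the subsampling draw (default 0).
#' @return A rarefied [otu_table()]; `provenance` records `depth`,
#'   `rarefaction_seed` and the number of OTUs dropped.
#' @export
rarefy <- function(x, depth = NULL, seed = 0) {
  stopifnot(inherits(x, "otu_table"))
  totals <- colSums(x$counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  shallow <- totals < depth
  if (any(shallow)) {
    stop(sprintf(
      "sample '%s' has %d reads, fewer than the requested depth %d",
      colnames(x$counts)[which(shallow)[1]], totals[which(shallow)[1]], depth
    ))
  }
  sub <- withr::with_seed(seed, {
    # vegan::rrarefy subsamples rows without replacement (mothur
    # sub.sample semantics); our samples are columns. Its advisory about
    # non-observed-looking counts is muffled: depth is validated above.
    withCallingHandlers(
      t(vegan::rrarefy(t(x$counts), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  storage.mode(sub) <- "integer"
  keep <- rowSums(sub) > 0
  dropped <- sum(!keep)
  out <- otu_table(sub[keep, , drop = FALSE], x$metadata, x$taxonomy, x$provenance)
  if (!is.null(out$taxonomy)) {
    out$taxonomy <- out$taxonomy[out$taxonomy$otu_id %in% rownames(out$counts), ]
  }
  out$provenance$depth <- depth
  out$provenance$rarefaction_seed <- seed
  out$provenance$otus_dropped_at_rarefaction <- dropped
  out
}
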