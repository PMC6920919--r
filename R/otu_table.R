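#' Construct an OTU table object
#'
#' Bundles a non-negative integer read-count matrix (rows = OTUs, columns =
#' samples) with per-sample metadata and optional per-OTU taxonomy. This is
#' the container every analysis step in the package consumes.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   rownames (OTU ids) and colnames (sample ids), or a data frame with OTU
#'   ids in the first column.
#' @param metadata Data frame with columns `sample_id`, `source`
#'   (`"leaf"`/`"air"`), `habitat` (plant species, or `"air"` for air
#'   samples) and `season` (`"summer"`/`"winter"`). Every sample in `counts`
#'   must have exactly one metadata row; metadata rows for unknown samples
#'   are dropped with a warning.
#' @param taxonomy Optional data frame with column `otu_id` and any lineage
#'   columns (typically `domain`, `phylum`, `class`, `order`,
#'   `closest_relative`).
#' @param provenance Optional named list recording processing history
#'   (depth, seed, removed OTU counts); carried along by the filtering and
#'   rarefaction steps.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `metadata` (tibble), `taxonomy` (tibble or `NULL`)
#'   and `provenance` (list).
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL, provenance = list()) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("`counts` must carry OTU ids as rownames and sample ids as colnames")
  }
  if (nrow(counts) == 0 && is.null(rownames(counts))) {
    rownames(counts) <- character(0)
  }
  storage.mode(counts) <- "double"
  bad <- which(counts < 0 | counts != floor(counts) | is.na(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at OTU '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  storage.mode(counts) <- "integer"
  if (anyDuplicated(rownames(counts))) stop("duplicated OTU ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")

  metadata <- as_tibble(metadata)
  req <- c("sample_id", "source", "habitat", "season")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent) > 0) {
    stop("missing metadata for sample(s): ", paste(absent, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, colnames(counts))
  if (length(extra) > 0) {
    warning("metadata for unknown sample(s) ignored: ", paste(extra, collapse = ", "))
    metadata <- metadata[metadata$sample_id %in% colnames(counts), ]
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (!all(metadata$source %in% c("leaf", "air"))) {
    stop("metadata source must be 'leaf' or 'air'")
  }
  if (!all(metadata$season %in% c("summer", "winter"))) {
    stop("metadata season must be 'summer' or 'winter'")
  }
  if (!all((metadata$habitat == "air") == (metadata$source == "air"))) {
    stop("habitat must be 'air' exactly for air-source samples")
  }

  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"otu_id" %in% names(taxonomy)) stop("taxonomy lacks column otu_id")
    taxonomy$otu_id <- as.character(taxonomy$otu_id)
  }

  structure(
    list(counts = counts, metadata = metadata, taxonomy = taxonomy,
         provenance = provenance),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "<otu_table> %d OTUs x %d samples (%s reads)\n",
    nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")
  ))
  src <- table(x$metadata$source, x$metadata$season)
  cat("samples:\n")
  print(src)
  if (!is.null(x$taxonomy)) cat(sprintf("taxonomy: %d OTUs annotated\n", nrow(x$taxonomy)))
  if (length(x$provenance) > 0) {
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Tidy an OTU table into long form
#'
#' @param x An [otu_table()].
#' @param ... Unused.
#' @return A tibble with columns `otu_id`, `sample_id`, `count`, joined with
#'   the sample metadata.
#' @export
tidy.otu_table <- function(x, ...) {
  long <- tibble(
    otu_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  dplyr::left_join(long, x$metadata, by = "sample_id")
}

#' @rdname tidy.otu_table
#' @export
glance.otu_table <- function(x, ...) {
  tibble(
    n_otus = nrow(x$counts),
    n_samples = ncol(x$counts),
    total_reads = sum(x$counts),
    min_sample_reads = min(colSums(x$counts)),
    max_sample_reads = max(colSums(x$counts))
  )
}

#' Read an OTU table, metadata and taxonomy from TSV files
#'
#' The count table is tab-separated with OTU ids in the first column and
#' sample ids in the header row. Metadata columns: `sample_id`, `source`,
#' `habitat`, `season`. Taxonomy columns: `otu_id` plus lineage fields.
#'
#' @param table_path Path to the count TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param taxonomy_path Optional path to the taxonomy TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(table_path, metadata_path, taxonomy_path = NULL) {
  counts <- readr::read_tsv(table_path, show_col_types = FALSE)
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  taxonomy <- if (!is.null(taxonomy_path)) {
    readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  }
  otu_table(counts, metadata, taxonomy)
}

#' Write an OTU table (and companions) to TSV files
#'
#' @param x An [otu_table()].
#' @param table_path Destination for the count TSV.
#' @param metadata_path Optional destination for the metadata TSV.
#' @param taxonomy_path Optional destination for the taxonomy TSV.
#' @param provenance_path Optional destination for a JSON provenance sidecar.
#' @return `x`, invisibly.
#' @export
write_otu_table <- function(x, table_path, metadata_path = NULL,
                            taxonomy_path = NULL, provenance_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  df <- dplyr::bind_cols(
    tibble(otu_id = rownames(x$counts)),
    as_tibble(as.data.frame(x$counts))
  )
  readr::write_tsv(df, table_path)
  if (!is.null(metadata_path)) readr::write_tsv(x$metadata, metadata_path)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    readr::write_tsv(x$taxonomy, taxonomy_path)
  }
  if (!is.null(provenance_path)) {
    jsonlite::write_json(x$provenance, provenance_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}

# subset an otu_table to given OTUs / samples, keeping metadata and taxonomy
# in step
subset_otu_table <- function(x, otus = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  taxonomy <- x$taxonomy
  if (!is.null(taxonomy) && !is.null(otus)) {
    taxonomy <- taxonomy[taxonomy$otu_id %in% rownames(counts), ]
  }
  otu_table(counts, x$metadata[x$metadata$sample_id %in% colnames(counts), ],
            taxonomy, x$provenance)
}
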