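#' Construct an OTU table
#'
#' The central container of the package: a samples-by-taxa matrix of
#' non-negative integer counts, an optional taxonomy table giving the
#' seven-rank lineage of each taxon, and an optional per-sample metadata
#' table describing the field design (cropping system, topographic position,
#' plot, date, year, soil origin).
#'
#' @param counts integer matrix, samples in rows, taxa in columns; both
#'   dimensions must be named and names must be unique.
#' @param taxonomy a data frame with column `otu_id` plus the seven rank
#'   columns `kingdom`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species` (empty string for unassigned ranks). `NULL` means no taxonomy;
#'   an all-empty lineage is assumed for every taxon.
#' @param metadata a data frame with column `sample_id` (one row per sample)
#'   plus any design columns. `NULL` means no metadata.
#' @return an object of class `otu_table`.
#' @export
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' otu_table(m)
otu_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must have sample (row) and taxon (column) names", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (is.null(taxonomy)) {
    taxonomy <- empty_taxonomy(colnames(counts))
  } else {
    taxonomy <- tibble::as_tibble(taxonomy)
  }
  if (!is.null(metadata)) metadata <- tibble::as_tibble(metadata)
  x <- structure(
    list(counts = counts, taxonomy = taxonomy, metadata = metadata),
    class = "otu_table"
  )
  validate_otu_table(x)
}

#' @rdname otu_table
#' @param x an object to test or validate.
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

validate_otu_table <- function(x) {
  counts <- x$counts
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0L)) stop("counts must be non-negative integers", call. = FALSE)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate otu_id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  tax <- x$taxonomy
  need <- c("otu_id", tax_ranks())
  if (!all(need %in% names(tax))) {
    stop("taxonomy must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!setequal(tax$otu_id, colnames(counts)) || nrow(tax) != ncol(counts)) {
    stop("taxonomy otu_id set does not match count matrix columns", call. = FALSE)
  }
  # keep taxonomy aligned with column order
  x$taxonomy <- tax[match(colnames(counts), tax$otu_id), ]
  if (!is.null(x$metadata)) {
    md <- x$metadata
    if (!"sample_id" %in% names(md)) {
      stop("metadata must have a sample_id column", call. = FALSE)
    }
    missing <- setdiff(rownames(counts), md$sample_id)
    if (length(missing)) {
      stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x$metadata <- md[match(rownames(counts), md$sample_id), ]
  }
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", nrow(x$counts), " samples x ", ncol(x$counts), " taxa\n",
      sep = "")
  tot <- rowSums(x$counts)
  cat("  library size: ", min(tot), "-", max(tot),
      " (mean ", round(mean(tot), 1), ")\n", sep = "")
  if (!is.null(x$metadata)) {
    cat("  metadata: ", paste(setdiff(names(x$metadata), "sample_id"),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample identifiers and library sizes
#' @param x an `otu_table`.
#' @return `sample_ids()`: character vector; `library_sizes()`: named integer
#'   vector of per-sample totals; `taxon_ids()`: character vector.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @rdname sample_ids
#' @export
library_sizes <- function(x) rowSums(x$counts)

#' Subset an OTU table by samples
#'
#' Keeps the taxonomy intact and subsets metadata rows to match.
#'
#' @param x an `otu_table`.
#' @param samples character vector of sample ids or logical/integer index.
#' @return an `otu_table` with the selected samples.
#' @export
filter_samples <- function(x, samples) {
  counts <- x$counts[samples, , drop = FALSE]
  md <- x$metadata
  if (!is.null(md)) md <- md[match(rownames(counts), md$sample_id), ]
  otu_table(counts, x$taxonomy, md)
}

#' Subset an OTU table by taxa
#' @param x an `otu_table`.
#' @param taxa character vector of taxon ids or logical/integer index.
#' @return an `otu_table` with the selected taxa.
#' @export
filter_taxa <- function(x, taxa) {
  counts <- x$counts[, taxa, drop = FALSE]
  tax <- x$taxonomy[match(colnames(counts), x$taxonomy$otu_id), ]
  otu_table(counts, tax, x$metadata)
}

#' Long-format view of an OTU table
#'
#' @param x an `otu_table`.
#' @param ... unused.
#' @return a tibble with one row per (sample, taxon) pair: `sample_id`,
#'   `otu_id`, `count`, joined with metadata columns when present.
#' @export
as_tibble.otu_table <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(rownames(x$counts), times = ncol(x$counts)),
    otu_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  if (!is.null(x$metadata)) {
    out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  }
  out
}

#' @export
tidy.otu_table <- function(x, ...) as_tibble.otu_table(x, ...)

#' @export
glance.otu_table <- function(x, ...) {
  tot <- rowSums(x$counts)
  tibble::tibble(
    n_samples = nrow(x$counts),
    n_taxa = ncol(x$counts),
    min_library = min(tot),
    max_library = max(tot),
    mean_library = mean(tot)
  )
}

empty_taxonomy <- function(otu_ids) {
  tax <- tibble::tibble(otu_id = otu_ids)
  for (r in tax_ranks()) tax[[r]] <- ""
  tax
}
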