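#' Drop low-count taxa
#'
#' Retains exactly the taxa whose total count across all samples is at least
#' `min_total`; the sample set is unchanged. The default of 2 removes
#' singleton OTUs, the usual guard against spurious clusters.
#'
#' @param x an [otu_table()].
#' @param min_total minimum total count across samples (>= 1).
#' @return the filtered `otu_table`; an empty taxon set is allowed.
#' @export
filter_min_count <- function(x, min_total = 2L) {
  stopifnot(is_otu_table(x), min_total >= 1)
  keep <- colSums(x$counts) >= min_total
  message("filter_min_count: ", sum(keep), "/", length(keep),
          " taxa retained (min_total = ", min_total, ")")
  filter_taxa(x, keep)
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same lineage prefix up to `level`.
#' Taxa unassigned at `level` are kept as explicit `unclassified_<parent>`
#' groups (one per parent prefix) rather than discarded, so per-sample
#' totals are preserved exactly.
#'
#' The collapsed table's taxonomy keeps the lineage up to `level` and blanks
#' the ranks below it.
#'
#' @param x an [otu_table()].
#' @param level one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return an `otu_table` with one column per taxonomic group at `level`.
#' @export
collapse_taxonomy <- function(x, level = "order") {
  stopifnot(is_otu_table(x))
  level <- match.arg(level, tax_ranks())
  keys <- collapse_keys(x$taxonomy, level)
  groups <- split(seq_len(ncol(x$counts)), keys$key)
  labels <- keys$label[!duplicated(keys$key)]
  names(labels) <- keys$key[!duplicated(keys$key)]
  counts <- vapply(
    groups,
    function(idx) as.integer(rowSums(x$counts[, idx, drop = FALSE])),
    integer(nrow(x$counts))
  )
  if (nrow(x$counts) == 1L) counts <- matrix(
    counts, nrow = 1L, dimnames = list(rownames(x$counts), names(groups))
  )
  colnames(counts) <- unname(labels[colnames(counts)])
  rownames(counts) <- rownames(x$counts)
  idx_level <- match(level, tax_ranks())
  tax <- x$taxonomy[vapply(groups, `[`, integer(1), 1L), ]
  tax$otu_id <- unname(labels[names(groups)])
  for (r in tax_ranks()[-seq_len(idx_level)]) tax[[r]] <- ""
  message("collapse_taxonomy: ", ncol(x$counts), " taxa -> ", ncol(counts),
          " groups at ", level, " level")
  otu_table(counts, tax, x$metadata)
}

#' Rarefy samples to a common depth
#'
#' Each retained sample's counts are replaced by a uniform subsample
#' WITHOUT replacement of its reads down to `depth`, so each taxon's
#' post-rarefaction count follows the (multivariate) hypergeometric
#' distribution and its expected proportion is unchanged. A sample whose
#' total already equals `depth` is returned as-is.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample (default 6678).
#' @param seed optional integer; when given, the subsampling runs in a local
#'   RNG scope and is reproducible.
#' @param drop_small if `TRUE` (default) samples with fewer than `depth`
#'   reads are dropped with a message; if `FALSE` they raise an error.
#' @return an `otu_table` in which every sample sums to exactly `depth`.
#' @export
rarefy <- function(x, depth = 6678L, seed = NULL, drop_small = TRUE) {
  stopifnot(is_otu_table(x), depth >= 1)
  depth <- as.integer(depth)
  totals <- rowSums(x$counts)
  small <- totals < depth
  if (any(small)) {
    if (!drop_small) {
      stop("sample(s) below rarefaction depth ", depth, ": ",
           paste(rownames(x$counts)[small], collapse = ", "), call. = FALSE)
    }
    message("rarefy: dropping ", sum(small), " sample(s) below depth ", depth,
            ": ", paste(rownames(x$counts)[small], collapse = ", "))
    x <- filter_samples(x, !small)
    totals <- totals[!small]
  }
  do_draw <- function() {
    counts <- x$counts
    for (s in seq_len(nrow(counts))) {
      if (totals[s] == depth) next
      reads <- rep.int(seq_len(ncol(counts)), counts[s, ])
      kept <- sample(reads, depth, replace = FALSE)
      counts[s, ] <- tabulate(kept, nbins = ncol(counts))
    }
    counts
  }
  counts <- if (is.null(seed)) do_draw() else withr::with_seed(seed, do_draw())
  message("rarefy: ", nrow(counts), " samples rarefied to depth ", depth)
  otu_table(counts, x$taxonomy, x$metadata)
}
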