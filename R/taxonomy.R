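#' The seven taxonomic ranks
#'
#' Rank names used throughout the package, ordered from kingdom to species.
#' Lineages follow the Greengenes convention: seven semicolon-separated
#' fields with single-letter prefixes (`k__`, `p__`, `c__`, `o__`, `f__`,
#' `g__`, `s__`); a rank may be empty anywhere, not only as a suffix.
#'
#' @return character vector of length 7.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

rank_prefixes <- function() c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse a Greengenes-style lineage string
#'
#' Splits a semicolon-separated lineage into the seven ranks, stripping
#' `k__`-style prefixes and surrounding whitespace. Missing trailing ranks
#' are filled with empty strings; an empty input yields an all-empty lineage.
#'
#' @param s a single lineage string, e.g.
#'   `"k__Bacteria; p__Nitrospirae; c__Nitrospira; o__Nitrospirales"`.
#' @return named character vector of length 7 (names from [tax_ranks()]).
#' @export
#' @examples
#' parse_lineage("k__Bacteria; p__Nitrospirae; c__Nitrospira; o__Nitrospirales")
parse_lineage <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  s <- trimws(s)
  out <- rep("", 7L)
  names(out) <- tax_ranks()
  if (is.na(s) || s == "") return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (length(parts) > 7L) {
    stop("lineage has ", length(parts), " fields (max 7): ", s, call. = FALSE)
  }
  parts <- sub("^[kpcofgs]__", "", parts)
  out[seq_along(parts)] <- parts
  out
}

#' Format a lineage as a Greengenes string
#'
#' Inverse of [parse_lineage()]: joins the seven ranks with `"; "` and
#' restores the single-letter prefixes.
#'
#' @param ranks character vector of length 7 (kingdom ... species).
#' @return a single lineage string.
#' @export
format_lineage <- function(ranks) {
  stopifnot(length(ranks) == 7L)
  paste0(rank_prefixes(), ranks, collapse = "; ")
}

#' Parse many lineage strings into a taxonomy table
#'
#' @param otu_ids character vector of taxon ids.
#' @param lineages character vector of lineage strings, same length
#'   (`NA` or `""` gives an all-empty lineage).
#' @return a taxonomy tibble (`otu_id` + the seven rank columns).
#' @export
parse_taxonomy <- function(otu_ids, lineages) {
  stopifnot(length(otu_ids) == length(lineages))
  mat <- t(vapply(lineages, parse_lineage, character(7)))
  tax <- tibble::as_tibble(mat)
  names(tax) <- tax_ranks()
  dplyr::bind_cols(tibble::tibble(otu_id = otu_ids), tax)
}

# Group key for collapsing at `level`: the lineage prefix up to that rank.
# Taxa unassigned at `level` fall in an explicit unclassified group under
# their parent prefix, so distinct parents never merge.
collapse_keys <- function(taxonomy, level) {
  ranks <- tax_ranks()
  level <- match.arg(level, ranks)
  idx <- match(level, ranks)
  prefix <- as.matrix(taxonomy[, ranks[seq_len(idx)], drop = FALSE])
  at_level <- prefix[, idx]
  empty <- at_level == ""
  key <- apply(prefix, 1L, paste, collapse = ";")
  label <- at_level
  if (any(empty)) {
    parent <- if (idx > 1L) {
      apply(prefix[, seq_len(idx - 1L), drop = FALSE], 1L, function(r) {
        nz <- r[r != ""]
        if (length(nz)) nz[length(nz)] else "root"
      })
    } else {
      rep("root", nrow(prefix))
    }
    label[empty] <- paste0("unclassified_", parent[empty])
  }
  # a label shared by two different prefixes must stay distinguishable
  u <- !duplicated(key)
  n_keys <- tapply(key[u], label[u], length)
  amb <- label %in% names(n_keys)[n_keys > 1L]
  label[amb] <- key[amb]
  tibble::tibble(key = key, label = label)
}
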