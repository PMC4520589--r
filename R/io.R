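#' Read an OTU table from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{the classic QIIME-1 tab-separated layout: one header row of
#'     sample ids, first column the OTU id (header `#OTU ID` or `otu_id`),
#'     optional last column `taxonomy` holding a semicolon-separated
#'     Greengenes lineage. An optional leading `# Constructed from biom file`
#'     comment line is ignored.}
#'   \item{`biom`}{BIOM-JSON format version 1.0 (sparse or dense), read via
#'     the biomformat package.}
#' }
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`; default guesses from the extension.
#' @param metadata optional path to a sample-metadata TSV
#'   (see [read_sample_metadata()]).
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  x <- switch(format,
    tsv = read_otu_tsv(path),
    biom = read_otu_biom(path)
  )
  if (!is.null(metadata)) {
    x <- otu_table(x$counts, x$taxonomy, read_sample_metadata(metadata))
  }
  x
}

read_otu_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  if (!length(lines)) stop("empty OTU table: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("malformed header in ", path, ": need otu_id column plus >=1 sample",
         call. = FALSE)
  }
  if (!header[1] %in% c("#OTU ID", "otu_id", "OTU_ID", "OTU ID")) {
    stop("malformed header in ", path, ": first column must be the OTU id, got '",
         header[1], "'", call. = FALSE)
  }
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_cols <- header[seq(2L, length(header) - has_tax)]
  if (anyDuplicated(sample_cols)) {
    stop("duplicate sample id in header: ",
         paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "),
         call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_field <- length(header)
  otu_ids <- character(length(body))
  lineages <- rep(NA_character_, length(body))
  counts <- matrix(0L, nrow = length(body), ncol = length(sample_cols))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_field) {
      stop("row ", i + 1L, " of ", path, " has ", length(row),
           " fields, expected ", n_field, call. = FALSE)
    }
    otu_ids[i] <- row[1]
    vals <- row[seq(2L, 1L + length(sample_cols))]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad)) {
      stop("non-integer count '", vals[bad[1]], "' at row ", i + 1L,
           " (otu '", row[1], "'), column '", sample_cols[bad[1]], "' of ",
           path, call. = FALSE)
    }
    counts[i, ] <- as.integer(num)
    if (has_tax) lineages[i] <- row[n_field]
  }
  if (anyDuplicated(otu_ids)) {
    stop("duplicate otu_id: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(otu_ids, sample_cols)
  tax <- if (has_tax) {
    parse_taxonomy(otu_ids, ifelse(is.na(lineages), "", lineages))
  } else {
    NULL
  }
  otu_table(t(counts), tax)
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the biomformat package is required for BIOM input", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b)) # taxa x samples
  storage.mode(counts) <- "integer"
  om <- biomformat::observation_metadata(b)
  tax <- NULL
  if (!is.null(om) && length(om)) {
    lineages <- if (is.data.frame(om)) {
      apply(om, 1L, function(r) paste(r[!is.na(r) & r != ""], collapse = "; "))
    } else {
      vapply(om, function(r) paste(unlist(r), collapse = "; "), character(1))
    }
    tax <- parse_taxonomy(rownames(counts), unname(lineages))
  }
  otu_table(t(counts), tax)
}

#' Write an OTU table to disk
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @param format `"tsv"` (classic layout, taxonomy column included when any
#'   lineage is non-empty) or `"biom"` (BIOM-JSON v1.0).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    counts <- t(x$counts) # taxa x samples
    tax_strings <- apply(
      as.matrix(x$taxonomy[, tax_ranks()]), 1L, function(r) format_lineage(r)
    )
    has_tax <- any(as.matrix(x$taxonomy[, tax_ranks()]) != "")
    header <- c("#OTU ID", colnames(counts), if (has_tax) "taxonomy")
    rows <- vapply(seq_len(nrow(counts)), function(i) {
      paste(c(rownames(counts)[i], counts[i, ], if (has_tax) tax_strings[i]),
            collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required for BIOM output", call. = FALSE)
    }
    obs_md <- data.frame(
      as.matrix(x$taxonomy[, tax_ranks()]),
      row.names = x$taxonomy$otu_id, check.names = FALSE
    )
    names(obs_md) <- paste0("taxonomy", 1:7)
    b <- biomformat::make_biom(
      data = t(x$counts), observation_metadata = obs_md
    )
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with a `sample_id` column and any design columns; the
#' supported designs use `cropping_system`, `topographic_position`, `plot`,
#' `date`, `year`, and `soil_origin`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(md)) {
    stop("metadata file ", path, " lacks a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in ", path, call. = FALSE)
  }
  md
}

#' @rdname read_sample_metadata
#' @param md a metadata data frame.
#' @export
write_sample_metadata <- function(md, path) {
  readr::write_tsv(md, path, progress = FALSE)
  invisible(path)
}
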