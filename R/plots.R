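#' Plot an NMDS ordination
#'
#' Scatter of the first two ordination axes, optionally coloured and shaped
#' by metadata columns, with the stress printed in the subtitle.
#'
#' @param object an `nmds_ordination` from [nmds()].
#' @param metadata optional data frame with `sample_id` to join for the
#'   aesthetics.
#' @param colour,shape metadata column names (strings) mapped to the
#'   corresponding aesthetics.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nmds_ordination <- function(object, metadata = NULL, colour = NULL,
                                     shape = NULL, ...) {
  pts <- object$points
  if (!is.null(metadata)) {
    pts <- dplyr::left_join(pts, tibble::as_tibble(metadata), by = "sample_id")
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  map <- if (!is.null(colour) && !is.null(shape)) {
    ggplot2::aes(colour = .data[[colour]], shape = .data[[shape]])
  } else if (!is.null(colour)) {
    ggplot2::aes(colour = .data[[colour]])
  } else if (!is.null(shape)) {
    ggplot2::aes(shape = .data[[shape]])
  } else {
    ggplot2::aes()
  }
  p +
    ggplot2::geom_point(map, size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' Plot delta-rank estimates with bootstrap intervals
#'
#' One point (mean delta-rank) with its bootstrap interval per taxon,
#' faceted by reporting unit. Positive values indicate a higher rank (more
#' dominant) in the whole soil; negative values a higher rank in the
#' rhizosphere. By default only taxa significant in at least one unit are
#' shown.
#'
#' @param object a `delta_rank_result` from [delta_rank()].
#' @param significant_only show only taxa whose interval excludes 0 in some
#'   unit (default TRUE).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.delta_rank_result <- function(object, significant_only = TRUE, ...) {
  tab <- object$table
  if (significant_only) {
    keep <- unique(tab$taxon[!is.na(tab$significant) & tab$significant])
    tab <- tab[tab$taxon %in% keep, ]
  }
  if (!nrow(tab)) stop("nothing to plot: no significant taxa", call. = FALSE)
  unit <- if (object$by == "position") "topographic_position" else NULL
  p <- ggplot2::ggplot(
    tab,
    ggplot2::aes(.data$mean_delta, stats::reorder(.data$taxon, .data$mean_delta))
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::labs(
      x = "Δ rank (rhizosphere − whole); positive = higher rank in whole soil",
      y = NULL, colour = "CI excludes 0"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(unit)) p <- p + ggplot2::facet_wrap(unit)
  p
}

#' Boxplots of an alpha-diversity metric by a design factor
#'
#' @param data output of [alpha_diversity()].
#' @param metric `"richness"`, `"shannon"` or `"evenness"`.
#' @param by a metadata column name.
#' @return a ggplot object.
#' @export
plot_alpha_diversity <- function(data, metric = "shannon", by) {
  stopifnot(metric %in% names(data), by %in% names(data))
  ggplot2::ggplot(
    data, ggplot2::aes(.data[[by]], .data[[metric]], fill = .data[[by]])
  ) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Rank-abundance curves for a pair of samples
#'
#' Whittaker-style plot of log abundance against rank for chosen samples,
#' the visual the paired rank-shift statistic summarizes.
#'
#' @param x an [otu_table()] (usually collapsed to the analysis level).
#' @param samples character vector of sample ids to draw.
#' @return a ggplot object.
#' @export
plot_rank_abundance <- function(x, samples = sample_ids(x)) {
  stopifnot(is_otu_table(x))
  long <- as_tibble(x) |>
    dplyr::filter(.data$sample_id %in% samples, .data$count > 0) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rank = rank(-.data$count, ties.method = "average")) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    long, ggplot2::aes(.data$rank, .data$count, colour = .data$sample_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "count (log scale)") +
    ggplot2::theme_minimal()
}
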