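#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{D_{xy} = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, a hollow symmetric
#' matrix with entries in \[0, 1\]. On tables with equal per-sample totals
#' (e.g. rarefied) the counts are used directly; on tables with unequal
#' totals the default converts to proportions first so library size does not
#' masquerade as composition.
#'
#' @param x an [otu_table()], or a samples-by-taxa numeric matrix.
#' @param normalize `"auto"` (proportions unless totals are all equal),
#'   `"counts"`, or `"proportions"`.
#' @return a `dist` object labelled with sample ids.
#' @export
bray_curtis <- function(x, normalize = c("auto", "counts", "proportions")) {
  normalize <- match.arg(normalize)
  m <- if (is_otu_table(x)) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least two samples", call. = FALSE)
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  }
  use_prop <- switch(normalize,
    auto = length(unique(tot)) > 1L,
    counts = FALSE,
    proportions = TRUE
  )
  if (use_prop) m <- m / tot
  vegan::vegdist(m, method = "bray")
}

#' Write / read a dissimilarity matrix as square labelled TSV
#'
#' @param d a `dist` object.
#' @param path file path.
#' @return `path` (write) or a `dist` (read), invisibly for write.
#' @export
write_dissimilarity <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Partitions the sum of squares of a distance matrix over a full-factorial
#' design (sequential/Type I terms) and tests each term's pseudo-F against a
#' free-permutation null, with the add-one convention
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. Non-significant
#' interaction terms (permutation p above `prune_alpha`) are removed
#' iteratively, highest order first, and the model refit — the same pruning
#' protocol as [fit_alpha_anova()].
#'
#' @param d a `dist` object (e.g. from [bray_curtis()]).
#' @param metadata data frame with `sample_id` matching `labels(d)` plus the
#'   design columns.
#' @param factors character vector of factor columns; the model is their
#'   full crossing.
#' @param n_perm number of permutations (default 9999).
#' @param prune_alpha interaction-pruning threshold (default 0.1); `NULL`
#'   disables pruning.
#' @param strata optional metadata column restricting permutations to within
#'   its levels; default free permutation.
#' @param seed optional integer for reproducible permutations.
#' @return an object of class `permanova` with a [tidy()] method.
#' @export
permanova <- function(d, metadata, factors, n_perm = 9999, prune_alpha = 0.1,
                      strata = NULL, seed = NULL) {
  stopifnot(inherits(d, "dist"), n_perm >= 1)
  ids <- labels(d)
  if (is.null(ids)) stop("dissimilarity matrix lacks sample labels", call. = FALSE)
  md <- as.data.frame(metadata)
  if (!"sample_id" %in% names(md)) stop("metadata needs sample_id", call. = FALSE)
  missing <- setdiff(ids, md$sample_id)
  if (length(missing)) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md <- md[match(ids, md$sample_id), , drop = FALSE]
  stopifnot(all(factors %in% names(md)))
  for (f in factors) {
    md[[f]] <- factor(md[[f]])
    if (nlevels(md[[f]]) < 2) {
      stop("factor '", f, "' is constant across samples", call. = FALSE)
    }
  }
  perm_arg <- if (is.null(strata)) {
    n_perm
  } else {
    permute::how(blocks = md[[strata]], nperm = n_perm)
  }

  run <- function() {
    form <- stats::as.formula(paste("d ~", paste(factors, collapse = " * ")))
    fit <- vegan::adonis2(form, data = md, permutations = perm_arg,
                          by = "terms")
    pruned <- tibble::tibble(term = character(), p.value = numeric())
    if (!is.null(prune_alpha)) {
      repeat {
        labels_ <- setdiff(rownames(fit), c("Residual", "Total"))
        cand <- removable_terms(labels_)
        if (!length(cand)) break
        p <- fit[cand, "Pr(>F)"]
        p[is.na(p)] <- Inf
        ord <- term_order(cand)
        drop_ok <- which(p > prune_alpha)
        if (!length(drop_ok)) break
        pick <- drop_ok[order(-ord[drop_ok], -p[drop_ok])][1]
        pruned <- dplyr::bind_rows(
          pruned, tibble::tibble(term = cand[pick], p.value = p[pick])
        )
        form <- stats::update(form, paste(". ~ . -", cand[pick]))
        fit <- vegan::adonis2(form, data = md, permutations = perm_arg,
                              by = "terms")
      }
    }
    list(fit = fit, pruned = pruned, form = form)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  tab <- tibble::tibble(
    term = rownames(res$fit),
    df = res$fit$Df,
    sumsq = res$fit$SumOfSqs,
    r.squared = res$fit$R2,
    statistic = res$fit$`F`,
    p.value = res$fit$`Pr(>F)`
  )
  structure(
    list(table = tab, pruned = res$pruned, n_perm = n_perm, seed = seed,
         formula = res$form, factors = factors, prune_alpha = prune_alpha),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("<permanova> ", x$n_perm, " permutations\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  if (nrow(x$pruned)) {
    cat("pruned interactions:",
        paste0(x$pruned$term, " (p=", signif(x$pruned$p.value, 3), ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) x$table

#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    n_terms = sum(!x$table$term %in% c("Residual", "Total")),
    n_pruned = nrow(x$pruned)
  )
}

#' Non-metric multidimensional scaling
#'
#' Embeds the samples in `k` dimensions minimizing Kruskal's stress-1 via
#' monotone regression of configuration distances on the rank order of the
#' input dissimilarities, taking the best of `n_restarts` random starts.
#'
#' @param d a `dist` object.
#' @param k embedding dimension (default 2; must be < number of samples).
#' @param n_restarts random starts (default 20).
#' @param max_iter iterations per start (default 200).
#' @param seed optional integer for reproducible starts.
#' @return an object of class `nmds_ordination`: `$points` (tibble of
#'   `sample_id` + `NMDS1..NMDSk`), `$stress` (in \[0, 1\]), `$converged`.
#'   Has [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 200, seed = NULL) {
  stopifnot(inherits(d, "dist"), k >= 1, k < attr(d, "Size"))
  run <- function() {
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (!isTRUE(fit$converged)) {
    warning("NMDS did not converge within ", n_restarts,
            " restarts; returning best solution found (stress = ",
            signif(fit$stress, 4), ")", call. = FALSE)
  }
  pts <- tibble::as_tibble(fit$points, rownames = "sample_id")
  names(pts)[-1] <- paste0("NMDS", seq_len(k))
  structure(
    list(points = pts, stress = fit$stress, k = k,
         converged = isTRUE(fit$converged), n_restarts = n_restarts,
         seed = seed, engine = fit),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("<nmds_ordination> k = ", x$k, ", stress = ", signif(x$stress, 4),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, converged = x$converged,
                 n_restarts = x$n_restarts)
}
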