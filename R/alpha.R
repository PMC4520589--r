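#' Shannon diversity of a count vector
#'
#' \eqn{H' = -\sum_i p_i \log p_i} over taxa with positive counts, where
#' \eqn{p_i} is the taxon's proportion of the total. Natural log by default.
#'
#' @param counts non-negative count vector with at least one positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return a single non-negative number, bounded above by `log(S, base)` for
#'   `S` observed taxa.
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero count vector", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Observed richness
#'
#' Number of taxa with a positive count.
#'
#' @param counts non-negative count vector.
#' @return an integer.
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' Pielou evenness
#'
#' \eqn{J' = H'/\ln S} (Shannon in nats over its maximum). Undefined for
#' communities with one or zero observed taxa, reported as `NA`.
#'
#' @param counts non-negative count vector.
#' @return a number in `[0, 1]`, or `NA` when fewer than two taxa are
#'   observed.
#' @export
evenness <- function(counts) {
  s <- richness(counts)
  if (s <= 1) return(NA_real_)
  shannon(counts) / log(s)
}

#' Per-sample alpha diversity
#'
#' Computes richness, Shannon's H' and Pielou evenness for every sample and
#' joins the sample metadata, ready for modelling.
#'
#' @param x an [otu_table()].
#' @param base logarithm base for Shannon (default natural log).
#' @return a tibble with columns `sample_id`, `richness`, `shannon`,
#'   `evenness`, plus any metadata columns.
#' @export
alpha_diversity <- function(x, base = exp(1)) {
  stopifnot(is_otu_table(x))
  out <- tibble::tibble(
    sample_id = rownames(x$counts),
    richness = apply(x$counts, 1L, richness),
    shannon = apply(x$counts, 1L, shannon, base = base),
    evenness = apply(x$counts, 1L, evenness)
  )
  if (!is.null(x$metadata)) {
    out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  }
  out
}

interaction_terms <- function(labels) labels[grepl(":", labels, fixed = TRUE)]

term_order <- function(label) lengths(strsplit(label, ":", fixed = TRUE))

# an interaction is removable only if no remaining term strictly contains it
removable_terms <- function(labels) {
  ints <- interaction_terms(labels)
  sets <- strsplit(labels, ":", fixed = TRUE)
  names(sets) <- labels
  ints[vapply(ints, function(t) {
    s <- sets[[t]]
    !any(vapply(labels, function(o) {
      length(sets[[o]]) > length(s) && all(s %in% sets[[o]])
    }, logical(1)))
  }, logical(1))]
}

#' Full-factorial ANOVA with interaction pruning and Tukey HSD
#'
#' Fits a fixed-effects ANOVA with the full crossing of `factors`, then
#' iteratively removes non-significant interaction terms: at each step the
#' removable interaction (one not marginal to a retained higher-order
#' interaction) with the largest p-value above `prune_alpha` is dropped,
#' highest order first, and the model is refit. Main effects are never
#' removed. Sums of squares are sequential (Type I), which coincides with
#' every other type under the balanced designs this package targets.
#' Tukey's HSD is run on each retained factor with three or more levels.
#'
#' @param data a data frame holding the response and the factor columns
#'   (e.g. the output of [alpha_diversity()]).
#' @param response name of the numeric response column.
#' @param factors character vector of factor column names to cross.
#' @param prune_alpha interactions with p above this are pruned
#'   (default 0.1); `NULL` disables pruning.
#' @param normalize `"none"` (default) or `"zscore"` (centre and scale the
#'   response before fitting; F and p are unchanged under a linear
#'   transformation, so this only affects effect-size scales).
#' @return an object of class `alpha_anova` with [tidy()], [glance()] and
#'   `$tukey` / `$pruned` components.
#' @export
fit_alpha_anova <- function(data, response, factors, prune_alpha = 0.1,
                            normalize = c("none", "zscore")) {
  normalize <- match.arg(normalize)
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  df <- as.data.frame(data[, c(response, factors)])
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2) {
      stop("factor '", f, "' is constant across samples", call. = FALSE)
    }
  }
  y <- df[[response]]
  if (anyNA(y)) stop("response '", response, "' contains NA", call. = FALSE)
  if (normalize == "zscore") df[[response]] <- as.numeric(scale(y))

  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(form, data = df)
  pruned <- tibble::tibble(term = character(), p.value = numeric())

  if (!is.null(prune_alpha)) {
    repeat {
      at <- stats::anova(fit)
      labels <- setdiff(rownames(at), "Residuals")
      cand <- removable_terms(labels)
      if (!length(cand)) break
      p <- at[cand, "Pr(>F)"]
      p[is.na(p)] <- Inf # inestimable term (no residual df): always prune
      ord <- term_order(cand)
      drop_ok <- which(p > prune_alpha)
      if (!length(drop_ok)) break
      # highest order first, then largest p
      pick <- drop_ok[order(-ord[drop_ok], -p[drop_ok])][1]
      pruned <- dplyr::bind_rows(
        pruned, tibble::tibble(term = cand[pick], p.value = p[pick])
      )
      form <- stats::update(form, paste(". ~ . -", cand[pick]))
      fit <- stats::lm(form, data = df)
    }
  }

  at <- stats::anova(fit)
  tab <- tibble::tibble(
    term = rownames(at),
    df = at$Df,
    sumsq = at$`Sum Sq`,
    meansq = at$`Mean Sq`,
    statistic = at$`F value`,
    p.value = at$`Pr(>F)`
  )
  if (at["Residuals", "Df"] <= 0) stop("zero residual df", call. = FALSE)

  tukey <- tibble::tibble(term = character(), contrast = character(),
                          estimate = numeric(), conf.low = numeric(),
                          conf.high = numeric(), adj.p.value = numeric())
  final_factors <- intersect(factors, attr(stats::terms(fit), "term.labels"))
  multi <- final_factors[vapply(final_factors,
                                function(f) nlevels(df[[f]]) > 2, logical(1))]
  if (length(multi)) {
    av <- stats::aov(form, data = df)
    th <- stats::TukeyHSD(av, which = multi)
    for (f in multi) {
      m <- th[[f]]
      tukey <- dplyr::bind_rows(tukey, tibble::tibble(
        term = f, contrast = rownames(m), estimate = m[, "diff"],
        conf.low = m[, "lwr"], conf.high = m[, "upr"],
        adj.p.value = m[, "p adj"]
      ))
    }
  }

  structure(
    list(model = fit, anova = tab, pruned = pruned, tukey = tukey,
         response = response, factors = factors, prune_alpha = prune_alpha,
         normalize = normalize),
    class = "alpha_anova"
  )
}

#' @export
print.alpha_anova <- function(x, ...) {
  cat("<alpha_anova> response:", x$response, "\n")
  print(as.data.frame(x$anova), digits = 4)
  if (nrow(x$pruned)) {
    cat("pruned interactions:",
        paste0(x$pruned$term, " (p=", signif(x$pruned$p.value, 3), ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.alpha_anova <- function(x, ...) x$anova

#' @export
glance.alpha_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$model$df.residual,
    n_pruned = nrow(x$pruned)
  )
}
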