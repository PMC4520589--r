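#' Run the full community-analysis pipeline from a config
#'
#' Orchestrates every stage — simulate or read an OTU table, minimum-count
#' filter, rarefaction, taxonomic collapsing, alpha-diversity ANOVAs,
#' Bray-Curtis/PERMANOVA/NMDS, and the paired delta-rank bootstrap — and
#' writes tidy TSV tables. The whole bundle is a pure function of
#' `(inputs, config, seed)`: one master seed deterministically derives a
#' seed per stage.
#'
#' @param config a YAML file path or an equivalent named list. Recognized
#'   blocks (all optional unless noted):
#' \describe{
#'   \item{seed}{integer master seed (default 1).}
#'   \item{input}{`otu` (path), `format` (`tsv`/`biom`), `metadata` (path).
#'     Mutually exclusive with `simulation`.}
#'   \item{simulation}{`design` (`"2011"`/`"2012"`), `params` (arguments to
#'     [sim_params()]), `effects` (list of rows for [sim_effect()]).}
#'   \item{preprocess}{`min_count` (default 2), `depth` (default 6678),
#'     `level` (default `"order"`).}
#'   \item{alpha}{`factors` (default: every design factor with >=2 levels,
#'     excluding plot), `prune_alpha` (0.1), `normalize` (`"none"`), `base`
#'     (`"e"`, `"2"`, or `"10"`).}
#'   \item{beta}{`factors`, `permutations` (9999), `prune_alpha` (0.1),
#'     `nmds_k` (2), `nmds_restarts` (20).}
#'   \item{delta_rank}{`enabled` (auto: on when rhizosphere samples exist),
#'     `bootstraps` (10000), `conf` (0.95), `by` (`"position"`),
#'     `drilldown` (TRUE).}
#'   \item{unrarefied}{also run the ANOVAs and PERMANOVA on the un-rarefied
#'     table as a robustness check (default FALSE).}
#' }
#' @param out_dir output directory (created if needed); overrides a
#'   `out_dir` entry in the config. `NULL` skips writing.
#' @return (invisibly) a named list of all in-memory results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  master <- as.integer(cfg$seed %||% 1L)
  seeds <- withr::with_seed(master, sample.int(.Machine$integer.max - 1L, 6L))

  # --- input -----------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    eff <- sim_effect()
    if (!is.null(sim$effects)) {
      eff <- dplyr::bind_rows(lapply(sim$effects, function(e) {
        sim_effect(taxon = e$taxon, rank = e$rank %||% "order",
                   factor = e$factor %||% "soil_origin",
                   level = e$level %||% "rhizosphere", fold = e$fold)
      }))
    }
    params <- do.call(sim_params, c(sim$params %||% list(), list(effects = eff)))
    design <- sim_design(sim$design %||% "2012")
    gen <- generate_dataset(design, params, seed = seeds[1])
    raw <- gen$table
    truth <- gen$truth
  } else if (!is.null(cfg$input)) {
    raw <- read_otu_table(cfg$input$otu, format = cfg$input$format %||% "auto",
                          metadata = cfg$input$metadata)
    truth <- NULL
  } else {
    stop("config needs an `input` or a `simulation` block", call. = FALSE)
  }
  message("pipeline: input table ", nrow(raw$counts), " samples x ",
          ncol(raw$counts), " taxa")

  # --- preprocess ------------------------------------------------------
  pp <- cfg$preprocess %||% list()
  min_count <- pp$min_count %||% 2L
  depth <- pp$depth %||% 6678L
  level <- pp$level %||% "order"
  filtered <- filter_min_count(raw, min_count)
  rarefied <- rarefy(filtered, depth = depth, seed = seeds[2])
  collapsed <- collapse_taxonomy(rarefied, level)

  md <- rarefied$metadata
  default_factors <- if (!is.null(md)) {
    cand <- intersect(
      c("cropping_system", "topographic_position", "soil_origin",
        "date", "year"),
      names(md)
    )
    cand[vapply(cand, function(f) length(unique(md[[f]])) >= 2, logical(1))]
  } else {
    character()
  }

  # --- alpha -----------------------------------------------------------
  al <- cfg$alpha %||% list()
  base <- switch(as.character(al$base %||% "e"),
                 e = exp(1), "2" = 2, "10" = 10)
  alpha_tbl <- alpha_diversity(rarefied, base = base)
  a_factors <- al$factors %||% default_factors
  anovas <- list()
  if (length(a_factors) >= 1) {
    for (metric in c("richness", "shannon", "evenness")) {
      if (anyNA(alpha_tbl[[metric]])) next
      anovas[[metric]] <- fit_alpha_anova(
        alpha_tbl, metric, a_factors,
        prune_alpha = al$prune_alpha %||% 0.1,
        normalize = al$normalize %||% "none"
      )
    }
  }

  # --- beta ------------------------------------------------------------
  be <- cfg$beta %||% list()
  d <- bray_curtis(rarefied)
  b_factors <- be$factors %||% default_factors
  perm <- NULL
  if (length(b_factors) >= 1) {
    perm <- permanova(d, md, b_factors,
                      n_perm = be$permutations %||% 9999,
                      prune_alpha = be$prune_alpha %||% 0.1,
                      seed = seeds[3])
  }
  ord <- suppressWarnings(
    nmds(d, k = be$nmds_k %||% 2, n_restarts = be$nmds_restarts %||% 20,
         seed = seeds[4])
  )

  # --- delta rank ------------------------------------------------------
  dr_cfg <- cfg$delta_rank %||% list()
  dr_requested <- dr_cfg$enabled %||%
    (!is.null(md) && "soil_origin" %in% names(md) &&
       any(md$soil_origin == "rhizosphere"))
  dr <- NULL
  if (isTRUE(dr_requested)) {
    dr <- delta_rank(
      rarefied, level = level,
      B = dr_cfg$bootstraps %||% 10000,
      conf = dr_cfg$conf %||% 0.95,
      by = dr_cfg$by %||% "position",
      drilldown = dr_cfg$drilldown %||% TRUE,
      seed = seeds[5]
    )
  }

  # --- un-rarefied robustness check ------------------------------------
  unrarefied <- NULL
  if (isTRUE(cfg$unrarefied)) {
    anovas_u <- list()
    alpha_u <- alpha_diversity(filtered, base = base)
    if (length(a_factors) >= 1) {
      for (metric in c("richness", "shannon", "evenness")) {
        if (anyNA(alpha_u[[metric]])) next
        anovas_u[[metric]] <- fit_alpha_anova(
          alpha_u, metric, a_factors,
          prune_alpha = al$prune_alpha %||% 0.1,
          normalize = al$normalize %||% "none"
        )
      }
    }
    d_u <- bray_curtis(filtered) # unequal totals -> proportions
    perm_u <- if (length(b_factors) >= 1) {
      permanova(d_u, filtered$metadata, b_factors,
                n_perm = be$permutations %||% 9999,
                prune_alpha = be$prune_alpha %||% 0.1,
                seed = seeds[6])
    }
    unrarefied <- list(alpha = alpha_u, anovas = anovas_u, permanova = perm_u)
  }

  results <- list(
    raw = raw, filtered = filtered, rarefied = rarefied,
    collapsed = collapsed, truth = truth,
    alpha = alpha_tbl, anovas = anovas,
    bray_curtis = d, permanova = perm, nmds = ord,
    delta_rank = dr, unrarefied = unrarefied,
    config = cfg, seed = master
  )
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  invisible(results)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  write_otu_table(res$rarefied, file.path(out_dir, "otu_table_rarefied.tsv"))
  wt(res$alpha, "alpha_diversity")
  for (metric in names(res$anovas)) {
    a <- res$anovas[[metric]]
    wt(a$anova, paste0("anova_", metric))
    if (nrow(a$tukey)) wt(a$tukey, paste0("tukey_", metric))
    if (nrow(a$pruned)) wt(a$pruned, paste0("anova_", metric, "_pruned"))
  }
  write_dissimilarity(res$bray_curtis, file.path(out_dir, "bray_curtis.tsv"))
  if (!is.null(res$permanova)) {
    wt(res$permanova$table, "permanova")
    if (nrow(res$permanova$pruned)) wt(res$permanova$pruned, "permanova_pruned")
  }
  wt(res$nmds$points, "nmds_coordinates")
  wt(glance(res$nmds), "nmds_summary")
  if (!is.null(res$delta_rank)) {
    wt(res$delta_rank$table, "delta_rank")
    wt(res$delta_rank$pairs, "delta_rank_pairs")
    for (lev in names(res$delta_rank$drilldown)) {
      tab <- res$delta_rank$drilldown[[lev]]
      if (!is.null(tab) && nrow(tab)) wt(tab, paste0("delta_rank_", lev))
    }
  }
  if (!is.null(res$unrarefied)) {
    for (metric in names(res$unrarefied$anovas)) {
      wt(res$unrarefied$anovas[[metric]]$anova,
         paste0("anova_", metric, "_unrarefied"))
    }
    if (!is.null(res$unrarefied$permanova)) {
      wt(res$unrarefied$permanova$table, "permanova_unrarefied")
    }
  }
  invisible(out_dir)
}
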