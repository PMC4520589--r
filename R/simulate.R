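#' Factorial sampling designs
#'
#' Construct the sample-metadata table for the two supported field designs,
#' or a custom crossing.
#'
#' `sim_design("2011")` is the within-season whole-soil design: 3 topographic
#' positions x 2 cropping systems x 3 plots x 3 dates (54 samples, all whole
#' soil, year 2011). `sim_design("2012")` is the paired whole/rhizosphere
#' design: 2 topographic positions (summit, toeslope) x 2 cropping systems x
#' 2 soil origins x 3 plots (24 samples, July 2012).
#'
#' @param design `"2011"`, `"2012"`, or `"custom"`.
#' @param topographic_position,cropping_system,soil_origin,plot,date,year
#'   level sets for a custom design (ignored otherwise).
#' @return a tibble with one row per sample: `sample_id` plus the design
#'   columns.
#' @export
sim_design <- function(design = c("2012", "2011", "custom"),
                       topographic_position = c("summit", "toeslope"),
                       cropping_system = c("annual", "perennial"),
                       soil_origin = "whole",
                       plot = 1:3, date = "July", year = 2012L) {
  design <- match.arg(design)
  if (design == "2011") {
    grid <- tidyr::expand_grid(
      topographic_position = c("summit", "backslope", "toeslope"),
      cropping_system = c("annual", "perennial"),
      plot = 1:3,
      date = c("June", "July", "August"),
      year = 2011L,
      soil_origin = "whole"
    )
  } else if (design == "2012") {
    grid <- tidyr::expand_grid(
      topographic_position = c("summit", "toeslope"),
      cropping_system = c("annual", "perennial"),
      soil_origin = c("whole", "rhizosphere"),
      plot = 1:3,
      date = "July",
      year = 2012L
    )
  } else {
    grid <- tidyr::expand_grid(
      topographic_position = topographic_position,
      cropping_system = cropping_system,
      soil_origin = soil_origin,
      plot = plot, date = date, year = year
    )
  }
  grid$plot <- paste0("p", grid$plot)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf(
      "Y%d_%s_%s_%s_%s_%s", grid$year, grid$date, grid$topographic_position,
      grid$cropping_system, grid$plot, substr(grid$soil_origin, 1, 4)
    )),
    grid
  )
}

#' Simulation parameters for the community generator
#'
#' Defines the taxonomic hierarchy sizes, the base composition, the
#' Dirichlet-multinomial dispersion, library-size variation, plot-level
#' compositional heterogeneity, and planted effects.
#'
#' The generative model, per sample: the base composition is (i) perturbed
#' by a plot-level lognormal offset shared by the whole/rhizosphere pair,
#' (ii) multiplied by any planted fold effects whose factor level matches the
#' sample, and renormalized; (iii) true proportions are drawn from a
#' Dirichlet with that mean and total concentration `concentration`; and
#' (iv) counts are multinomial at a library size drawn uniformly from
#' `library_size_range`.
#'
#' @param n_orders,families_per_order,genera_per_family,otus_per_genus
#'   hierarchy sizes; all must be >= 1.
#' @param base optional base composition over OTUs (positive, will be
#'   normalized). Default: geometric decay of rate `order_decay` across
#'   orders and 0.7 within the nested levels — a steep, realistic
#'   rank-abundance profile.
#' @param order_decay geometric ratio between successive orders' base
#'   abundances (default 0.88, i.e. ~13 rank positions per 5-fold abundance
#'   change).
#' @param concentration Dirichlet total concentration; larger means less
#'   compositional noise between replicate samples (default 200).
#' @param library_size_range integer pair; default `c(6678, 23359)`, the
#'   span typical of a MiSeq 16S run after quality filtering.
#' @param plot_sigma standard deviation (log scale) of the plot-level
#'   lognormal offset shared within a whole/rhizosphere pair (default 0.25).
#' @param effects a tibble of planted effects, see [sim_effect()].
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_orders = 30, families_per_order = 2,
                       genera_per_family = 2, otus_per_genus = 2,
                       base = NULL, order_decay = 0.88,
                       concentration = 200,
                       library_size_range = c(6678L, 23359L),
                       plot_sigma = 0.25,
                       effects = sim_effect()) {
  stopifnot(
    n_orders >= 1, families_per_order >= 1, genera_per_family >= 1,
    otus_per_genus >= 1, concentration > 0, plot_sigma >= 0,
    length(library_size_range) == 2, all(library_size_range >= 1),
    order_decay > 0
  )
  p <- list(
    n_orders = as.integer(n_orders),
    families_per_order = as.integer(families_per_order),
    genera_per_family = as.integer(genera_per_family),
    otus_per_genus = as.integer(otus_per_genus),
    base = base, order_decay = order_decay,
    concentration = concentration,
    library_size_range = as.integer(sort(library_size_range)),
    plot_sigma = plot_sigma,
    effects = tibble::as_tibble(effects)
  )
  class(p) <- "sim_params"
  p
}

#' Planted differential-abundance effects
#'
#' Each row multiplies the base abundance of every OTU descending from
#' `taxon` (matched at rank `rank`) by `fold` in samples whose metadata
#' column `factor` equals `level`, before renormalization. `fold > 1`
#' enriches the taxon in those samples; `fold < 1` depletes it.
#'
#' @param taxon taxon name(s), e.g. `"Order15"`.
#' @param rank rank at which `taxon` is matched (default `"order"`).
#' @param factor metadata column the effect is conditioned on.
#' @param level factor level in which the effect applies.
#' @param fold multiplicative fold, strictly positive.
#' @return a tibble with columns `taxon`, `rank`, `factor`, `level`, `fold`.
#' @export
#' @examples
#' sim_effect("Order15", fold = 5) # 5x rhizosphere enrichment of one order
sim_effect <- function(taxon = character(), rank = "order",
                       factor = "soil_origin", level = "rhizosphere",
                       fold = numeric()) {
  if (length(taxon) == 0) {
    return(tibble::tibble(taxon = character(), rank = character(),
                          factor = character(), level = character(),
                          fold = numeric()))
  }
  stopifnot(all(fold > 0))
  tibble::tibble(taxon = taxon, rank = rank, factor = factor,
                 level = level, fold = fold)
}

#' Build a synthetic taxonomy hierarchy
#'
#' Creates a rooted, non-overlapping hierarchy with the sizes given in
#' `params`: names are unique across the whole tree at every rank (e.g.
#' family `Order03_F1` belongs only to `Order03`), so collapsing at any rank
#' is well defined. Species is left unassigned, as is typical of
#' closed-reference OTUs.
#'
#' @param params a [sim_params()] object.
#' @return a taxonomy tibble (`otu_id` + seven rank columns) with
#'   `n_orders * families_per_order * genera_per_family * otus_per_genus`
#'   rows.
#' @export
build_taxonomy <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  grid <- tidyr::expand_grid(
    o = seq_len(params$n_orders),
    f = seq_len(params$families_per_order),
    g = seq_len(params$genera_per_family),
    u = seq_len(params$otus_per_genus)
  )
  order_name <- sprintf("Order%02d", grid$o)
  family_name <- sprintf("%s_F%d", order_name, grid$f)
  genus_name <- sprintf("%s_G%d", family_name, grid$g)
  tibble::tibble(
    otu_id = sprintf("OTU_%04d", seq_len(nrow(grid))),
    kingdom = "Bacteria",
    phylum = sprintf("Phylum%02d", (grid$o - 1L) %/% 5L + 1L),
    class = sprintf("Class%02d", grid$o),
    order = order_name,
    family = family_name,
    genus = genus_name,
    species = ""
  )
}

# Deterministic base composition over OTUs: geometric decay across orders,
# geometric(0.7) within each nested level.
default_base <- function(params) {
  grid <- tidyr::expand_grid(
    o = seq_len(params$n_orders), f = seq_len(params$families_per_order),
    g = seq_len(params$genera_per_family), u = seq_len(params$otus_per_genus)
  )
  w <- params$order_decay^(grid$o - 1L) * 0.7^(grid$f - 1L) *
    0.7^(grid$g - 1L) * 0.7^(grid$u - 1L)
  w / sum(w)
}

#' Draw one community count vector
#'
#' The elementary Dirichlet-multinomial draw: the base composition is
#' multiplied by `fold` taxon-wise and renormalized, true proportions are
#' drawn from a Dirichlet with that mean and total concentration
#' `concentration`, and counts are multinomial at `library_size`. The
#' expected proportion of taxon i is exactly
#' `base[i] * fold[i] / sum(base * fold)`.
#'
#' @param base positive composition vector (normalized internally).
#' @param concentration positive scalar; the Dirichlet parameter is
#'   `concentration * perturbed_base`.
#' @param library_size positive integer total count.
#' @param fold optional positive multiplicative perturbation, recycled to
#'   `length(base)`; default all 1.
#' @param seed optional integer; when given the draw is made in a local RNG
#'   scope, leaving the global RNG untouched.
#' @return integer vector of counts summing to `library_size`, with `base`'s
#'   names.
#' @export
sample_community <- function(base, concentration, library_size, fold = NULL,
                             seed = NULL) {
  stopifnot(all(base > 0), concentration > 0, library_size >= 1)
  if (is.null(fold)) fold <- 1
  fold <- rep_len(fold, length(base))
  stopifnot(all(fold > 0))
  draw <- function() {
    mean_p <- base * fold
    mean_p <- mean_p / sum(mean_p)
    g <- stats::rgamma(length(mean_p), shape = concentration * mean_p, rate = 1)
    p <- g / sum(g)
    counts <- as.integer(stats::rmultinom(1L, size = library_size, prob = p))
    names(counts) <- names(base)
    counts
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a full synthetic dataset
#'
#' Draws one sample per row of `design` under the model described in
#' [sim_params()]. Samples that differ only in `soil_origin` (a
#' whole/rhizosphere pair) share a plot-level lognormal composition offset,
#' so the pairing carries information; planted effects perturb only the
#' samples whose metadata matches.
#'
#' @param design a design tibble from [sim_design()].
#' @param params a [sim_params()] object.
#' @param seed integer seed; the dataset is a pure function of
#'   `(design, params, seed)`.
#' @return a list with elements
#'   \describe{
#'     \item{table}{an [otu_table()] with taxonomy and the design metadata;}
#'     \item{truth}{a list with `proportions` (samples x OTUs matrix of true
#'       expected proportions after offset and planted effects) and
#'       `effects` (the planted-effect tibble).}
#'   }
#' @export
generate_dataset <- function(design, params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  taxonomy <- build_taxonomy(params)
  base <- params$base
  if (is.null(base)) base <- default_base(params)
  stopifnot(length(base) == nrow(taxonomy), all(base > 0))
  base <- base / sum(base)

  eff <- params$effects
  if (nrow(eff)) {
    stopifnot(all(eff$rank %in% tax_ranks()))
    for (i in seq_len(nrow(eff))) {
      if (!any(taxonomy[[eff$rank[i]]] == eff$taxon[i])) {
        stop("planted effect references unknown taxon '", eff$taxon[i],
             "' at rank ", eff$rank[i], call. = FALSE)
      }
      if (!eff$factor[i] %in% names(design)) {
        stop("planted effect references unknown factor '", eff$factor[i], "'",
             call. = FALSE)
      }
    }
  }

  pair_cols <- intersect(
    c("topographic_position", "cropping_system", "plot", "date", "year"),
    names(design)
  )
  pair_key <- do.call(paste, c(design[pair_cols], sep = "|"))

  withr::with_seed(seed, {
    # one lognormal offset per pair group, shared across its members
    groups <- unique(pair_key)
    offsets <- matrix(
      stats::rlnorm(length(groups) * length(base), 0, params$plot_sigma),
      nrow = length(groups),
      dimnames = list(groups, NULL)
    )
    lib_sizes <- sample.int(
      params$library_size_range[2] - params$library_size_range[1] + 1L,
      nrow(design), replace = TRUE
    ) + params$library_size_range[1] - 1L

    counts <- matrix(0L, nrow(design), length(base),
                     dimnames = list(design$sample_id, taxonomy$otu_id))
    truth_p <- matrix(0, nrow(design), length(base),
                      dimnames = dimnames(counts))
    for (s in seq_len(nrow(design))) {
      fold <- rep(1, length(base))
      if (nrow(eff)) {
        for (i in seq_len(nrow(eff))) {
          if (design[[eff$factor[i]]][s] == eff$level[i]) {
            hit <- taxonomy[[eff$rank[i]]] == eff$taxon[i]
            fold[hit] <- fold[hit] * eff$fold[i]
          }
        }
      }
      b <- base * offsets[pair_key[s], ] * fold
      b <- b / sum(b)
      truth_p[s, ] <- b
      g <- stats::rgamma(length(b), shape = params$concentration * b, rate = 1)
      counts[s, ] <- as.integer(
        stats::rmultinom(1L, size = lib_sizes[s], prob = g / sum(g))
      )
    }
    list(
      table = otu_table(counts, taxonomy, design),
      truth = list(proportions = truth_p, effects = eff)
    )
  })
}
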