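# shared fixtures, all generated in code

tiny_table <- function() {
  m <- matrix(c(1L, 2L, 3L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB")))
  otu_table(m)
}

# random valid otu_table with taxonomy and trivial metadata
random_table <- function(seed, n_samples = 5, n_taxa = 8) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_taxa, 20), n_samples, n_taxa,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                paste0("otu", seq_len(n_taxa))))
    lin <- paste0(
      "k__Bacteria; p__P", sample(1:2, n_taxa, TRUE),
      "; c__C1; o__O", sample(1:3, n_taxa, TRUE),
      "; f__F", seq_len(n_taxa)
    )
    otu_table(m, parse_taxonomy(colnames(m), lin))
  })
}

# small paired whole/rhizosphere table built by hand: 2 positions x 2 crops
# x `plots` plots, one pair each, `n_taxa` taxa at "order" level already
paired_table <- function(counts_fun, plots = 3, n_taxa = 5, seed = 1) {
  md <- tidyr::expand_grid(
    topographic_position = c("summit", "toeslope"),
    cropping_system = c("annual", "perennial"),
    plot = paste0("p", seq_len(plots)),
    soil_origin = c("whole", "rhizosphere")
  )
  md$sample_id <- sprintf("%s_%s_%s_%s", md$topographic_position,
                          md$cropping_system, md$plot, md$soil_origin)
  withr::with_seed(seed, {
    m <- t(vapply(seq_len(nrow(md)),
                  function(i) counts_fun(md[i, ]),
                  integer(n_taxa)))
  })
  dimnames(m) <- list(md$sample_id, sprintf("Order%02d", seq_len(n_taxa)))
  tax <- tibble::tibble(
    otu_id = colnames(m), kingdom = "Bacteria", phylum = "P1", class = "C1",
    order = colnames(m), family = "", genus = "", species = ""
  )
  otu_table(m, tax, md)
}

# params for fast order-level simulations: one OTU per order (the order-level
# count distribution is unchanged by the Dirichlet aggregation property)
fast_params <- function(...) {
  sim_params(families_per_order = 1, genera_per_family = 1,
             otus_per_genus = 1, ...)
}

# independent double-loop oracle for Bray-Curtis
brute_bray <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  D
}
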