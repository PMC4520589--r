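test_that("rank profiles rank descending with average ties and bottom zeros", {
  expect_equal(unname(rank_profile(c(50, 30, 20))), c(1, 2, 3))
  expect_equal(unname(rank_profile(c(10, 10, 5))), c(1.5, 1.5, 3))
  expect_equal(unname(rank_profile(c(4, 0, 0))), c(1, 2.5, 2.5))
  r <- rank_profile(c(a = 5, b = 9, c = 1))
  expect_equal(sum(r), 6) # T(T+1)/2
  # permutation equivariance
  v <- c(7, 3, 3, 1, 9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(rank_profile(v[perm])), unname(rank_profile(v)[perm]))
})

test_that("paired deltas follow the whole-vs-rhizosphere sign convention", {
  # one pair; rank 2 in whole, rank 5 in rhizosphere for Order03
  whole <- c(90L, 50L, 40L, 30L, 20L) # Order03 (40) has rank 3... build exact
  # construct: whole ranks: O1=1 O2=2 O3=3 O4=4 O5=5; make O2 rank 2 whole
  counts_fun <- function(row) {
    if (row$soil_origin == "whole") c(90L, 50L, 40L, 30L, 20L)
    else c(90L, 10L, 40L, 30L, 20L) # O2 drops to rank 5 in rhizosphere
  }
  x <- paired_table(counts_fun, plots = 1)
  pr <- suppressWarnings(delta_rank_pairs(x))
  o2 <- pr[pr$taxon == "Order02", ]
  expect_true(all(o2$rank_whole == 2))
  expect_true(all(o2$rank_rhizosphere == 5))
  expect_true(all(o2$delta_rank == 3)) # positive: higher rank in whole soil
})

test_that("identical paired communities give all-zero deltas", {
  x <- paired_table(function(row) c(9L, 7L, 5L, 3L, 1L))
  pr <- delta_rank_pairs(x)
  expect_true(all(pr$delta_rank == 0))
})

test_that("swapping soil-origin labels negates every delta and mirrors CIs", {
  x <- paired_table(function(row) {
    base <- c(40L, 30L, 20L, 10L, 5L)
    jitter <- as.integer(sample(0:8, 5, replace = TRUE))
    base + jitter
  }, seed = 99)
  pr <- delta_rank_pairs(x)
  md2 <- x$metadata
  md2$soil_origin <- ifelse(md2$soil_origin == "whole", "rhizosphere", "whole")
  y <- otu_table(x$counts, x$taxonomy, md2)
  pr2 <- delta_rank_pairs(y)
  key <- paste(pr$taxon, pr$cropping_system, pr$topographic_position, pr$plot)
  key2 <- paste(pr2$taxon, pr2$cropping_system, pr2$topographic_position,
                pr2$plot)
  expect_equal(pr2$delta_rank[match(key, key2)], -pr$delta_rank)
  ci1 <- bootstrap_delta_rank(pr, B = 500, seed = 7)
  ci2 <- bootstrap_delta_rank(pr2, B = 500, seed = 7)
  expect_equal(ci2$ci_lo, -ci1$ci_hi, tolerance = 1e-12)
  expect_equal(ci2$ci_hi, -ci1$ci_lo, tolerance = 1e-12)
  expect_equal(ci2$significant, ci1$significant)
})

test_that("unpaired plots are skipped with a warning; missing pairs error", {
  x <- paired_table(function(row) c(9L, 7L, 5L, 3L, 1L))
  x1 <- filter_samples(x, sample_ids(x) != "summit_annual_p1_whole")
  expect_warning(delta_rank_pairs(x1), "summit.*p1")
  whole_only <- filter_samples(x, x$metadata$soil_origin == "whole")
  expect_error(delta_rank_pairs(whole_only), "rhizosphere")
})

test_that("constant deltas give a point interval, significant iff nonzero", {
  d <- tibble::tibble(
    taxon = "t", cropping_system = rep(c("a", "p"), each = 3),
    topographic_position = "summit", delta_rank = rep(2, 6)
  )
  ci <- bootstrap_delta_rank(d, B = 200, seed = 1)
  expect_equal(ci$ci_lo, 2)
  expect_equal(ci$ci_hi, 2)
  expect_true(ci$significant)
  d0 <- dplyr::mutate(d, delta_rank = 0)
  ci0 <- bootstrap_delta_rank(d0, B = 200, seed = 1)
  expect_equal(c(ci0$ci_lo, ci0$ci_hi), c(0, 0))
  expect_false(ci0$significant)
})

test_that("too few bootstrap draws or too few pairs are handled", {
  d <- tibble::tibble(
    taxon = "t", cropping_system = "a",
    topographic_position = "summit", delta_rank = c(1, 2)
  )
  expect_error(bootstrap_delta_rank(d, B = 50), "B < 100")
  d1 <- d[1, ]
  ci <- bootstrap_delta_rank(d1, B = 200, seed = 1)
  expect_true(is.na(ci$ci_lo))
  expect_true(ci$degenerate)
  expect_error(bootstrap_delta_rank(d, statistic = "median"), "studentized")
})

test_that("null symmetric deltas are rarely flagged", {
  set.seed(55)
  flags <- vapply(1:300, function(i) {
    d <- tibble::tibble(
      taxon = "t", cropping_system = rep(c("a", "p"), each = 3),
      topographic_position = "summit", delta_rank = rnorm(6, 0, 2)
    )
    isTRUE(bootstrap_delta_rank(d, B = 400)$significant)
  }, logical(1))
  expect_lte(mean(flags), 0.10)
})

test_that("bootstrap intervals are seed-reproducible across both units", {
  x <- paired_table(function(row) {
    as.integer(c(40, 30, 20, 10, 5) + sample(0:6, 5, TRUE))
  }, seed = 77)
  pr <- delta_rank_pairs(x)
  c1 <- bootstrap_delta_rank(pr, B = 300, seed = 5)
  c2 <- bootstrap_delta_rank(pr, B = 300, seed = 5)
  expect_identical(c1, c2)
  expect_setequal(unique(c1$topographic_position), c("summit", "toeslope"))
  c3 <- bootstrap_delta_rank(pr, B = 300, seed = 5, by = "stratum")
  expect_true("cropping_system" %in% names(c3))
  expect_equal(unique(c3$n), 3)
})

test_that("drill-down is restricted to descendants of significant orders", {
  p <- sim_params(n_orders = 6, families_per_order = 2, genera_per_family = 2,
                  otus_per_genus = 1,
                  effects = sim_effect("Order05", fold = 8))
  gen <- generate_dataset(sim_design("2012"), p, seed = 13)
  dr <- suppressMessages(suppressWarnings(
    delta_rank(gen$table, B = 500, seed = 13, drilldown = TRUE)
  ))
  expect_named(dr$drilldown, c("family", "genus"))
  sig <- unique(dr$table$taxon[!is.na(dr$table$significant) &
                                 dr$table$significant])
  fam <- dr$drilldown$family
  if (nrow(fam)) {
    expect_true(all(fam$parent %in% sig))
    # family names carry their order prefix in the synthetic taxonomy
    expect_true(all(startsWith(fam$taxon, fam$parent)))
  }
  gen_tab <- dr$drilldown$genus
  if (nrow(gen_tab)) expect_true(all(gen_tab$parent %in% sig))
})

test_that("drill-down on no significant orders is empty", {
  x <- paired_table(function(row) c(9L, 7L, 5L, 3L, 1L))
  out <- drilldown_delta_rank(x, character(0))
  expect_identical(out, list())
})

test_that("a planted genus-level enrichment surfaces in the drill-down", {
  p <- sim_params(n_orders = 8, families_per_order = 1, genera_per_family = 3,
                  otus_per_genus = 1,
                  effects = sim_effect("Order04_F1_G2", rank = "genus",
                                       fold = 12))
  gen <- generate_dataset(sim_design("2012"), p, seed = 21)
  dr <- suppressMessages(suppressWarnings(
    delta_rank(gen$table, B = 500, seed = 21, drilldown = TRUE)
  ))
  gt <- dr$drilldown$genus
  if (!is.null(gt) && nrow(gt)) {
    hit <- gt[gt$taxon == "Order04_F1_G2", ]
    expect_true(any(!is.na(hit$significant) & hit$significant &
                      hit$ci_hi < 0))
  } else {
    # the planted genus must at least flag its order
    expect_true("Order04" %in% dr$table$taxon[dr$table$significant])
  }
})

test_that("the full delta-rank wrapper is deterministic given a seed", {
  gen <- generate_dataset(sim_design("2012"), fast_params(), seed = 31)
  d1 <- suppressMessages(delta_rank(gen$table, B = 300, seed = 9))
  d2 <- suppressMessages(delta_rank(gen$table, B = 300, seed = 9))
  expect_identical(d1$table, d2$table)
  expect_s3_class(tidy(d1), "tbl_df")
  expect_equal(glance(d1)$level, "order")
})
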