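test_that("minimum-count filter keeps exactly the taxa at or above threshold", {
  m <- matrix(c(1L, 0L, 1L, 1L, 2L, 3L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  x <- otu_table(m)
  m2 <- matrix(c(1L, 2L, 5L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  y <- suppressMessages(filter_min_count(otu_table(m2), 2))
  expect_setequal(colnames(y$counts), c("t2", "t3"))
  expect_equal(rownames(y$counts), c("s1", "s2"))
  # min_total = 1 is the identity when no taxon is all-zero
  z <- suppressMessages(filter_min_count(x, 1))
  expect_identical(z$counts, x$counts)
})

test_that("filter agrees with a brute-force column-sum scan on random tables", {
  for (seed in 1:5) {
    x <- random_table(seed, n_samples = 6, n_taxa = 12)
    thr <- withr::with_seed(seed, sample(50:150, 1))
    kept <- suppressMessages(filter_min_count(x, thr))
    brute <- colnames(x$counts)[vapply(
      seq_len(ncol(x$counts)), function(j) sum(x$counts[, j]) >= thr,
      logical(1))]
    expect_setequal(as.character(colnames(kept$counts)), as.character(brute))
  }
})

test_that("taxonomic collapse sums within groups and preserves totals", {
  tax <- parse_taxonomy(
    paste0("o", 1:4),
    c("k__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1",
      "k__B; p__P1; c__C1; o__O1; f__F2; g__G2; s__S2",
      "k__B; p__P1; c__C1; o__O2; f__F3; g__G3; s__S3",
      "k__B; p__P1; c__C1; o__O2; f__F4; g__G4; s__S4")
  )
  m <- matrix(1:8, nrow = 2,
              dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  storage.mode(m) <- "integer"
  x <- otu_table(m, tax)
  co <- suppressMessages(collapse_taxonomy(x, "order"))
  expect_setequal(colnames(co$counts), c("O1", "O2"))
  expect_equal(unname(co$counts[, "O1"]), unname(m[, "o1"] + m[, "o2"]))
  expect_equal(rowSums(co$counts), rowSums(m))
  # species level with full lineages is a bijection
  sp <- suppressMessages(collapse_taxonomy(x, "species"))
  expect_equal(ncol(sp$counts), 4)
  expect_equal(sort(as.integer(sp$counts)), sort(as.integer(m)))
})

test_that("unclassified-at-level taxa form one group per parent prefix", {
  tax <- parse_taxonomy(
    paste0("o", 1:4),
    c("k__B; p__P1; c__C1; o__O1; f__",
      "k__B; p__P1; c__C1; o__O1; f__",
      "k__B; p__P1; c__C1; o__O2; f__",
      "k__B; p__P1; c__C1; o__O2; f__F1")
  )
  m <- matrix(1L, nrow = 2, ncol = 4,
              dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  x <- otu_table(m, tax)
  co <- suppressMessages(collapse_taxonomy(x, "family"))
  expect_equal(ncol(co$counts), 3) # unclassified_O1, unclassified_O2, F1
  expect_setequal(colnames(co$counts),
                  c("unclassified_O1", "unclassified_O2", "F1"))
  expect_equal(rowSums(co$counts), rowSums(m))
})

test_that("collapse preserves per-sample totals on random fixtures", {
  for (seed in 6:9) {
    x <- random_table(seed, n_samples = 4, n_taxa = 15)
    for (level in c("phylum", "order", "family")) {
      co <- suppressMessages(collapse_taxonomy(x, level))
      expect_equal(rowSums(co$counts), rowSums(x$counts))
    }
  }
})

test_that("rarefaction subsamples without replacement to exact depth", {
  m <- matrix(c(10L, 0L, 30L, 10L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  x <- otu_table(m)
  # sample at exactly the depth is returned unchanged
  r <- suppressMessages(rarefy(x, depth = 10, seed = 1, drop_small = FALSE))
  expect_equal(unname(r$counts["s1", ]), c(10, 0))
  expect_equal(sum(r$counts["s2", ]), 10)
  expect_true(all(r$counts <= m))
  # single-taxon support: always [5, 0]
  r5 <- suppressMessages(rarefy(filter_samples(x, "s1"), 5, seed = 2))
  expect_equal(unname(r5$counts[1, ]), c(5, 0))
})

test_that("rarefaction drops or refuses shallow samples as asked", {
  m <- matrix(c(10L, 0L, 30L, 10L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  x <- otu_table(m)
  r <- suppressMessages(rarefy(x, depth = 20, seed = 1))
  expect_equal(rownames(r$counts), "s2")
  expect_error(suppressMessages(rarefy(x, depth = 20, seed = 1,
                                       drop_small = FALSE)), "s1")
})

test_that("rarefied counts follow the hypergeometric law", {
  # draws of depth 20 from [30,10]: E = 15, var = 20*.75*.25*(20/39)
  m <- matrix(c(30L, 10L), 1, 2, dimnames = list("s", c("a", "b")))
  x <- otu_table(m)
  draws <- vapply(1:3000, function(s) {
    suppressMessages(rarefy(x, 20, seed = s))$counts[1, 1]
  }, integer(1))
  se <- sqrt(20 * 0.75 * 0.25 * (40 - 20) / (40 - 1)) / sqrt(3000)
  expect_lt(abs(mean(draws) - 15), 4 * se)
  expect_true(all(draws <= 20))
  # variance should also match, loosely
  expect_equal(var(draws), 20 * 0.75 * 0.25 * (40 - 20) / (40 - 1),
               tolerance = 0.15)
})

test_that("rarefaction is seed-reproducible", {
  x <- random_table(3, n_samples = 4, n_taxa = 10)
  r1 <- suppressMessages(rarefy(x, 100, seed = 11))
  r2 <- suppressMessages(rarefy(x, 100, seed = 11))
  expect_identical(r1$counts, r2$counts)
})
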