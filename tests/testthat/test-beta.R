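test_that("Bray-Curtis matches hand-evaluated cases", {
  m <- rbind(x = c(6, 2), y = c(2, 4))
  d <- as.matrix(bray_curtis(m, normalize = "counts"))
  expect_equal(d["x", "y"], 6 / 14)
  same <- rbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(as.matrix(bray_curtis(same, normalize = "counts"))["a", "b"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.matrix(bray_curtis(disj, normalize = "counts"))["a", "b"], 1)
})

test_that("all-zero samples are refused by name", {
  m <- rbind(ok = c(1, 2), bad = c(0, 0))
  expect_error(bray_curtis(m), "bad")
})

test_that("unequal library sizes trigger proportion normalization by default", {
  m <- rbind(a = c(10, 10), b = c(100, 100)) # same composition
  expect_equal(as.matrix(bray_curtis(m))["a", "b"], 0)
  expect_gt(as.matrix(bray_curtis(m, normalize = "counts"))["a", "b"], 0.7)
})

test_that("square-matrix TSV round-trips a dissimilarity", {
  x <- random_table(21, n_samples = 5)
  d <- bray_curtis(x)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(d, path)
  d2 <- read_dissimilarity(path)
  expect_equal(as.matrix(d2), as.matrix(d), tolerance = 1e-12)
})

test_that("PERMANOVA on univariate Euclidean data equals classical ANOVA", {
  set.seed(31)
  md <- tibble::tibble(sample_id = paste0("s", 1:18),
                       g = rep(c("a", "b", "c"), each = 6))
  y <- rnorm(18) + (md$g == "b")
  D <- stats::dist(y)
  attr(D, "Labels") <- md$sample_id
  fit <- permanova(D, md, "g", n_perm = 999, prune_alpha = NULL, seed = 1)
  classical <- anova(lm(y ~ g, data = md))
  expect_equal(fit$table$statistic[fit$table$term == "g"],
               classical$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$table$sumsq[fit$table$term == "g"],
               classical$`Sum Sq`[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are seed-reproducible and properly bounded", {
  x <- random_table(32, n_samples = 12, n_taxa = 20)
  md <- tibble::tibble(sample_id = rownames(x$counts),
                       g = rep(c("a", "b"), 6))
  d <- bray_curtis(x)
  f1 <- permanova(d, md, "g", n_perm = 199, seed = 9)
  f2 <- permanova(d, md, "g", n_perm = 199, seed = 9)
  expect_identical(f1$table, f2$table)
  p <- f1$table$p.value[f1$table$term == "g"]
  expect_gte(p, 1 / 200)
  expect_lte(p, 1)
})

test_that("the observed pseudo-F is invariant to sample reordering", {
  x <- random_table(33, n_samples = 10, n_taxa = 15)
  md <- tibble::tibble(sample_id = rownames(x$counts),
                       g = rep(c("a", "b"), 5))
  d <- bray_curtis(x)
  perm <- withr::with_seed(1, sample(10))
  m2 <- as.matrix(d)[perm, perm]
  d2 <- stats::as.dist(m2)
  f1 <- permanova(d, md, "g", n_perm = 99, seed = 2, prune_alpha = NULL)
  f2 <- permanova(d2, md, "g", n_perm = 99, seed = 2, prune_alpha = NULL)
  expect_equal(f1$table$statistic, f2$table$statistic, tolerance = 1e-12)
  expect_equal(f1$table$sumsq, f2$table$sumsq, tolerance = 1e-12)
})

test_that("PERMANOVA interaction pruning follows the ANOVA protocol", {
  gen <- generate_dataset(sim_design("2012"), fast_params(), seed = 5)
  d <- bray_curtis(suppressMessages(rarefy(gen$table, 6678, seed = 5)))
  fit <- permanova(d, gen$table$metadata,
                   c("cropping_system", "soil_origin"),
                   n_perm = 99, prune_alpha = 1e-9, seed = 1)
  expect_false(any(grepl(":", fit$table$term)))
  expect_equal(nrow(fit$pruned), 1)
})

test_that("distance SS partition sums to the total", {
  x <- random_table(34, n_samples = 12, n_taxa = 18)
  md <- tibble::tibble(sample_id = rownames(x$counts),
                       g = rep(c("a", "b"), 6),
                       h = rep(c("u", "u", "v", "v"), 3))
  d <- bray_curtis(x)
  fit <- permanova(d, md, c("g", "h"), n_perm = 99, prune_alpha = NULL,
                   seed = 1)
  tot <- fit$table$sumsq[fit$table$term == "Total"]
  expect_equal(sum(fit$table$sumsq[fit$table$term != "Total"]), tot,
               tolerance = 1e-10)
  # Gower identity: total SS = sum of squared distances / n
  expect_equal(tot, sum(as.matrix(d)^2) / 2 / 12, tolerance = 1e-10)
})

test_that("NMDS recovers a perfectly embeddable configuration", {
  set.seed(41)
  pts <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), NULL))
  D <- stats::dist(pts)
  fit <- suppressWarnings(nmds(D, k = 2, n_restarts = 10, seed = 3))
  expect_lt(fit$stress, 1e-3)
  # configuration distances preserve the rank order of D
  conf <- as.matrix(fit$points[, c("NMDS1", "NMDS2")])
  rownames(conf) <- fit$points$sample_id
  dc <- as.vector(stats::dist(conf[labels(D), ]))
  expect_gt(cor(rank(dc), rank(as.vector(D))), 0.999)
})

test_that("three equidistant samples embed as an equilateral triangle", {
  D <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                             dimnames = list(letters[1:3], letters[1:3])))
  fit <- suppressWarnings(nmds(D, k = 2, n_restarts = 5, seed = 4))
  conf <- as.matrix(fit$points[, c("NMDS1", "NMDS2")])
  sides <- as.vector(stats::dist(conf))
  expect_lt(max(sides) - min(sides), 0.05 * mean(sides))
  expect_lt(fit$stress, 1e-3)
})

test_that("result objects expose tidy/glance views", {
  x <- random_table(35, n_samples = 8)
  md <- tibble::tibble(sample_id = rownames(x$counts),
                       g = rep(c("a", "b"), 4))
  d <- bray_curtis(x)
  fit <- permanova(d, md, "g", n_perm = 99, seed = 1)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_perm, 99)
  o <- suppressWarnings(nmds(d, seed = 1, n_restarts = 3))
  expect_s3_class(tidy(o), "tbl_df")
  expect_true(is.numeric(glance(o)$stress))
})
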