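test_that("build_feature_table assembles the canonical column counts", {
  coll <- fix_collection()
  expect_equal(ncol(build_feature_table(coll, sets = c("TD", "FD", "TF"))$features),
               1026L)
  full <- build_feature_table(coll)
  expect_equal(ncol(full$features), 1102L)
  expect_equal(nrow(full$features), 24L)
  # order is always TD, FD, TF, ND regardless of how sets are passed
  shuffled <- build_feature_table(coll, sets = c("ND", "TD"))
  doms <- parse_feature_ids(colnames(shuffled$features))$domain
  expect_identical(unique(doms), c("TD", "ND"))
  nd <- build_feature_table(generate_dataset(1, 2, seed = 5)[[1]], sets = "ND")
  expect_identical(dim(nd$features), c(12L, 76L))
  expect_error(build_feature_table(coll, sets = c("TD", "XX")), "unknown")
  expect_error(build_feature_table(list()), "empty")
})

test_that("anova_pvalue matches hand sums-of-squares and stats::oneway.test", {
  # identical groups: F = 0, p = 1
  expect_equal(anova_pvalue(list(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_error(anova_pvalue(list(1:3)), "at least 2")
  expect_error(anova_pvalue(list(1:3, 5)), ">= 2 values")
  # textbook 3-group dataset, brute-force between/within sums of squares
  g <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  all_y <- unlist(g)
  grand <- mean(all_y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  Fstat <- (ssb / 2) / (ssw / 15)
  expect_equal(anova_pvalue(g), pf(Fstat, 2, 15, lower.tail = FALSE))
  # and against the stats oracle on random instances
  set.seed(31)
  for (r in 1:20) {
    gs <- lapply(1:4, function(i) rnorm(sample(3:9, 1), mean = runif(1, 0, 2)))
    y <- unlist(gs); f <- factor(rep(seq_along(gs), lengths(gs)))
    expect_equal(anova_pvalue(gs),
                 oneway.test(y ~ f, var.equal = TRUE)$p.value)
  }
})

test_that("null ANOVA p-values are uniform (KS) and degenerate columns get p = 1", {
  set.seed(32)
  X <- matrix(rnorm(36 * 2000), nrow = 36)
  g <- rep(1:6, each = 6)
  p <- fingereeg:::.anova_pvalues(X, g)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # zero total variance -> never selected
  expect_equal(fingereeg:::.anova_pvalues(matrix(5, 36, 1), g)[1], 1)
  # perfect separation -> p ~ 0
  expect_lt(fingereeg:::.anova_pvalues(matrix(g, 36, 1), g)[1], 1e-12)
})

test_that("select_features flags p < alpha and validates the class design", {
  tab <- fix_nd_table()
  mask <- select_features(tab, alpha = 0.05)
  expect_s3_class(mask, "selection_mask")
  expect_identical(mask$significant, mask$p_value < 0.05)
  expect_equal(nrow(mask), 76L)
  none <- select_features(tab, alpha = 0)
  expect_equal(sum(none$significant), 0L)
  bad <- tab
  bad$label[bad$label == 3] <- 2
  expect_error(select_features(bad), "absent")
  # BH adjustment can only reduce the selection
  bh <- select_features(tab, adjust = "BH")
  expect_lte(sum(bh$significant), sum(mask$significant))
})

test_that("reduce_table keeps significant columns in order, flags empties", {
  tab <- fix_nd_table()
  mask <- select_features(tab, alpha = 0.05)
  red <- reduce_table(tab, mask)
  expect_equal(ncol(red$features), sum(mask$significant))
  expect_identical(colnames(red$features), mask$id[mask$significant])
  all_true <- mask; all_true$significant <- rep(TRUE, nrow(mask))
  expect_identical(reduce_table(tab, all_true)$features, tab$features)
  all_false <- mask; all_false$significant <- rep(FALSE, nrow(mask))
  empty <- reduce_table(tab, all_false)
  expect_true(isTRUE(attr(empty, "empty")))
  expect_equal(ncol(empty$features), 0L)
  expect_error(crossval(empty, classifier_spec("svm", "linear")), "empty")
})

test_that("distribution maps conserve mask counts in both modes", {
  tab <- fix_nd_table()
  mask <- select_features(tab, alpha = 0.2)
  map <- distribution_map(mask, "ND")
  expect_identical(dim(map$grid), c(4L, 19L))
  expect_equal(map$grand_total, sum(mask$significant))
  expect_equal(sum(map$row_totals), map$grand_total)
  expect_equal(sum(map$col_totals), map$grand_total)
  expect_true(all(map$grid %in% 0:1))
  # all-false mask -> all-zero map
  mask0 <- mask; mask0$significant <- rep(FALSE, nrow(mask))
  expect_equal(distribution_map(mask0, "ND")$grand_total, 0L)
  # count mode: 8 identical all-true masks -> every cell 8
  mask1 <- mask; mask1$significant <- rep(TRUE, nrow(mask))
  cmap <- distribution_map(rep(list(mask1), 8), "ND")
  expect_identical(cmap$mode, "count")
  expect_true(all(cmap$grid == 8L))
  expect_equal(cmap$grand_total, 8L * 4L * 19L)
  # mixed-domain mask is rejected; subset_mask fixes it
  full <- select_features(build_feature_table(fix_collection(),
                                              sets = c("TD", "ND")))
  expect_error(distribution_map(full, "ND"), "mixes")
  expect_equal(distribution_map(subset_mask(full, "ND"), "ND")$grand_total,
               sum(subset_mask(full, "ND")$significant))
})

test_that("tables, masks and maps round-trip through CSV/JSON", {
  dir <- withr::local_tempdir()
  tab <- fix_nd_table()
  p1 <- file.path(dir, "tab.csv")
  write_feature_table(tab, p1)
  back <- read_feature_table(p1)
  expect_equal(back$features, tab$features)
  expect_identical(back$label, tab$label)
  expect_identical(back$subject, tab$subject)
  mask <- select_features(tab, alpha = 0.1)
  p2 <- file.path(dir, "mask.json")
  write_mask(mask, p2)
  mback <- read_mask(p2)
  expect_equal(mback$p_value, mask$p_value)
  expect_identical(mback$significant, mask$significant)
  expect_equal(attr(mback, "alpha"), 0.1)
  map <- distribution_map(mask, "ND")
  p3 <- file.path(dir, "map.json")
  write_map(map, p3)
  j <- jsonlite::read_json(p3, simplifyVector = TRUE)
  expect_equal(j$grand_total, map$grand_total)
  expect_equal(j$schema_version, 1L)
  p4 <- file.path(dir, "map.csv")
  map_to_csv(map, p4)
  grid_csv <- read.csv(p4)
  expect_equal(nrow(grid_csv), 5L)        # 4 feature rows + totals row
  expect_equal(as.integer(grid_csv$Total[5]), map$grand_total)
})
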