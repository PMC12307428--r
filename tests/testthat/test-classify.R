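test_that("accuracy is trace over total with strict validation", {
  expect_equal(accuracy(diag(c(10, 20, 30))), 1)
  expect_equal(accuracy(matrix(c(50, 0, 0, 50), 2)), 1)
  # 6 classes, 60 on the diagonal out of 100 total
  cm <- matrix(0, 6, 6); cm[1, 2] <- 40; diag(cm) <- 10
  expect_equal(accuracy(cm), 0.6)
  expect_error(accuracy(matrix(1, 2, 3)), "square")
  expect_error(accuracy(matrix(-1, 2, 2)), "non-negative")
  expect_error(accuracy(matrix(0, 2, 2)), "total 0")
})

test_that("classifier_spec validates against the catalog", {
  ct <- classifier_catalog()
  expect_equal(length(unique(ct$family)), 8L)
  expect_s3_class(classifier_spec("knn", "cosine"), "classifier_spec")
  expect_error(classifier_spec("svm", "sigmoid"), "unknown")
  expect_error(classifier_spec("forest", "deep"), "unknown")
})

test_that("crossval is deterministic, stratified and accumulates a confusion", {
  tab <- fix_nd_table()
  spec <- classifier_spec("svm", "linear")
  r1 <- crossval(tab, spec, k = 4, seed = 9)
  r2 <- crossval(tab, spec, k = 4, seed = 9)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$mean_accuracy, mean(r1$fold_accuracies))
  # pooled confusion covers every segment once; rows = per-class counts
  expect_equal(sum(r1$confusion), nrow(tab$features))
  expect_equal(unname(rowSums(r1$confusion)), rep(4L, 6L), ignore_attr = TRUE)
  expect_error(crossval(tab, spec, k = 5), "at least k")
  # fold assignment balances classes within +-1
  folds <- fingereeg:::with_seed(3, fingereeg:::.stratified_folds(tab$label, 2))
  for (cl in 1:6)
    expect_lte(diff(range(tabulate(folds[tab$label == cl], 2))), 1L)
})

test_that("every classifier family fits and predicts on a small table", {
  tab <- fix_nd_table()                   # 24 segments, 4 per class
  for (fam_var in list(c("decision_tree", "coarse"),
                       c("discriminant", "linear"),
                       c("naive_bayes", "gaussian"),
                       c("svm", "medium_gaussian"),
                       c("knn", "cosine"),
                       c("ensemble", "subspace_knn"),
                       c("neural_net", "narrow"),
                       c("kernel_approx", "svm"))) {
    res <- crossval(tab, classifier_spec(fam_var[1], fam_var[2]),
                    k = 2, seed = 5)
    expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 1),
                info = paste(fam_var, collapse = "/"))
  }
})

test_that("a separable planted world is learned far above chance", {
  ds <- generate_dataset(1, 10, separable_cfg(8), seed = 41)
  tab <- build_feature_table(ds[[1]], sets = "FD")
  res <- crossval(tab, classifier_spec("svm", "linear"), k = 5, seed = 1)
  expect_gt(res$mean_accuracy, 0.5)       # chance is 1/6
})

test_that("run_grid covers the cells, records failures as NA, summarizes best", {
  tab <- fix_nd_table()
  specs <- list(classifier_spec("svm", "linear"),
                classifier_spec("discriminant", "quadratic"))  # qda will fail
  grid <- run_grid(list(ND = tab), specs, k = 2, seed = 3,
                   reduced = TRUE, alpha = 0.2)
  # 2 specs x (full + reduced) x 2 folds
  expect_equal(nrow(grid), 8L)
  expect_true(all(is.na(grid$accuracy) |
                  (grid$accuracy >= 0 & grid$accuracy <= 1)))
  expect_true(all(is.na(grid$mean_accuracy[grid$family == "discriminant"])))
  expect_true(all(!is.na(grid$mean_accuracy[grid$family == "svm"])))
  # deterministic under the master seed
  grid2 <- run_grid(list(ND = tab), specs, k = 2, seed = 3,
                    reduced = TRUE, alpha = 0.2)
  expect_identical(grid$accuracy, grid2$accuracy)
  s <- summarize_grid(grid)
  expect_equal(nrow(s), 4L)               # 2 families x full/reduced
  expect_true(all(s$best_variant[s$family == "svm"] == "linear"))
  expect_true(all(is.na(s$best_variant[s$family == "discriminant"])))
  # an empty reduced table becomes NA rows rather than an error
  null_tab <- tab
  null_tab$features <- matrix(rnorm(24 * 5), 24,
                              dimnames = list(NULL, paste0("ND:ND1:ch", 1:5)))
  g2 <- run_grid(list(x = null_tab), list(classifier_spec("svm", "linear")),
                 k = 2, seed = 1, reduced = TRUE, alpha = 1e-12)
  expect_true(all(is.na(g2$accuracy[g2$reduced])))
  expect_true(all(!is.na(g2$accuracy[!g2$reduced])))
})

test_that("best-of-variants reporting picks the true maximum", {
  # synthetic grid: hand-build rows and check the aggregation convention
  grid <- data.frame(
    feature_set = "S", reduced = FALSE,
    family = rep(c("svm", "knn"), each = 4),
    variant = rep(c("a", "a", "b", "b"), 2),
    fold = rep(1:2, 4),
    accuracy = c(0.5, 0.6, 0.7, 0.8, 0.2, 0.4, 0.9, 0.1),
    mean_accuracy = c(0.55, 0.55, 0.75, 0.75, 0.3, 0.3, 0.5, 0.5),
    seed = 1)
  s <- summarize_grid(grid)
  expect_equal(s$best_variant[s$family == "svm"], "b")
  expect_equal(s$mean_accuracy[s$family == "svm"], 0.75)
  expect_equal(s$best_variant[s$family == "knn"], "b")
})
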