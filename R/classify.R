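#' The classifier family/variant catalog
#'
#' The eight families and their variants benchmarked by the pipeline:
#' decision trees (fine/medium/coarse), discriminant analysis
#' (linear/quadratic), naive Bayes (gaussian/kernel), support vector
#' machines (linear/quadratic/cubic and fine/medium/coarse Gaussian,
#' implemented as one-vs-rest least-squares kernel machines), k-nearest
#' neighbours (cubic/cosine), ensembles (boosted/bagged/subspace
#' discriminant/subspace kNN/RUSBoosted trees), neural networks
#' (narrow/medium/wide/bi-/tri-layered) and kernel approximation
#' (random-Fourier-feature SVM/logistic). Hyperparameters approximate
#' common GUI presets and are fixed in `.variant_presets()`.
#'
#' @return data.frame with columns `family`, `variant`.
#' @export
classifier_catalog <- function() {
  fam <- list(
    decision_tree = c("fine", "medium", "coarse"),
    discriminant = c("linear", "quadratic"),
    naive_bayes = c("gaussian", "kernel"),
    svm = c("linear", "quadratic", "cubic",
            "fine_gaussian", "medium_gaussian", "coarse_gaussian"),
    knn = c("cubic", "cosine"),
    ensemble = c("boosted", "bagged", "subspace_discriminant",
                 "subspace_knn", "rusboosted"),
    neural_net = c("narrow", "medium", "wide", "bilayered", "trilayered"),
    kernel_approx = c("svm", "logistic")
  )
  data.frame(family = rep(names(fam), lengths(fam)),
             variant = unlist(fam, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# families whose inputs are z-scored on the training folds
.scale_sensitive <- c("svm", "knn", "neural_net", "kernel_approx")

.variant_presets <- function(family, variant, p) {
  switch(family,
    decision_tree = list(max_splits = c(fine = 100L, medium = 20L,
                                        coarse = 4L)[[variant]]),
    discriminant = list(quadratic = identical(variant, "quadratic")),
    naive_bayes = list(kernel = identical(variant, "kernel")),
    svm = switch(variant,
      linear = list(kernel = "linear", degree = 1, scale = sqrt(p)),
      quadratic = list(kernel = "poly", degree = 2, scale = sqrt(p)),
      cubic = list(kernel = "poly", degree = 3, scale = sqrt(p)),
      fine_gaussian = list(kernel = "rbf", degree = 1, scale = sqrt(p) / 4),
      medium_gaussian = list(kernel = "rbf", degree = 1, scale = sqrt(p)),
      coarse_gaussian = list(kernel = "rbf", degree = 1, scale = 4 * sqrt(p))),
    knn = switch(variant,
      cubic = list(k = 10L, metric = "minkowski3"),
      cosine = list(k = 10L, metric = "cosine")),
    ensemble = list(kind = variant),
    neural_net = list(hidden = switch(variant,
      narrow = c(10L), medium = c(25L), wide = c(100L),
      bilayered = c(10L, 10L), trilayered = c(10L, 10L, 10L))),
    kernel_approx = list(variant = variant),
    stop("unknown classifier family: ", family)
  )
}

#' Construct a classifier specification
#'
#' @param family,variant a pair from [classifier_catalog()].
#' @param hyperparameters optional named list overriding the preset values.
#' @return A `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("svm", "linear")
classifier_spec <- function(family, variant, hyperparameters = list()) {
  cat_tbl <- classifier_catalog()
  ok <- cat_tbl$family == family & cat_tbl$variant == variant
  if (!any(ok))
    stop("unknown classifier family/variant: ", family, "/", variant)
  structure(list(family = family, variant = variant,
                 hyperparameters = hyperparameters),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s/%s\n", x$family, x$variant))
  invisible(x)
}

.fit_classifier <- function(spec, X, y) {
  hp <- modifyList(.variant_presets(spec$family, spec$variant, ncol(X)),
                   spec$hyperparameters)
  switch(spec$family,
    decision_tree = .tree_fit(X, y, max_splits = hp$max_splits),
    discriminant = .da_fit(X, y, quadratic = hp$quadratic),
    naive_bayes = .nb_fit(X, y, kernel = hp$kernel),
    svm = .lssvm_fit(X, y, kernel = hp$kernel, scale = hp$scale,
                     degree = hp$degree),
    knn = .knn_fit(X, y, k = hp$k, metric = hp$metric),
    ensemble = switch(hp$kind,
      boosted = .boost_fit(X, y),
      bagged = .bag_fit(X, y),
      subspace_discriminant = .subspace_fit(X, y, "discriminant"),
      subspace_knn = .subspace_fit(X, y, "knn"),
      rusboosted = .boost_fit(X, y, rus = TRUE)),
    neural_net = .mlp_fit(X, y, hidden = hp$hidden),
    kernel_approx = .rff_fit(X, y, variant = hp$variant)
  )
}

#' Classification accuracy from a confusion matrix
#'
#' Multi-class accuracy as trace over total; for the 2 x 2 case this is
#' literally (TP + TN) / (TP + FN + TN + FP).
#'
#' @param confusion square matrix of non-negative counts, rows = truth.
#' @return Accuracy in [0, 1].
#' @export
#' @examples
#' accuracy(matrix(c(50, 0, 0, 50), 2))  # 1
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) < 1L)
    stop("confusion must be a non-empty square matrix")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion must contain non-negative integer counts")
  tot <- sum(confusion)
  if (tot == 0) stop("confusion matrix is empty (total 0)")
  sum(diag(confusion)) / tot
}

# deterministic stratified fold assignment
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits the table into k stratified folds (seeded), z-scores features on
#' the training folds only for scale-sensitive families (SVM, kNN, neural
#' nets, kernel approximation), fits on k-1 folds and scores the held-out
#' fold. The pooled confusion matrix accumulates over folds.
#'
#' @param table a `feature_table`.
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the split and any learner
#'   randomness.
#' @return A `cv_result`: `fold_accuracies`, `mean_accuracy`, `confusion`
#'   (classes x classes, rows = truth), `spec`, `seed`.
#' @export
crossval <- function(table, spec, k = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "classifier_spec"),
            k >= 2L)
  if (isTRUE(attr(table, "empty")) || ncol(table$features) == 0L)
    stop("empty feature table: no columns to classify on")
  if (anyNA(table$features)) stop("feature table contains missing values")
  counts <- table(table$label)
  if (any(counts < k))
    stop("every class needs at least k segments (k = ", k, ")")
  classes <- sort(unique(table$label))
  y <- factor(table$label, levels = classes)
  X <- table$features
  with_seed(seed, {
    folds <- .stratified_folds(table$label, k)
    conf <- matrix(0L, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
      if (spec$family %in% .scale_sensitive) {
        mu <- colMeans(Xtr)
        sds <- apply(Xtr, 2, sd)
        sds[sds == 0 | !is.finite(sds)] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sds, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sds, "/")
      }
      model <- .fit_classifier(spec, Xtr, y[tr])
      pred <- model$predict(Xte)
      truth <- as.integer(y[!tr])
      cm <- matrix(0L, length(classes), length(classes))
      for (i in seq_along(pred)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
      conf <- conf + cm
      fold_acc[f] <- sum(diag(cm)) / sum(cm)
    }
    structure(list(fold_accuracies = fold_acc,
                   mean_accuracy = mean(fold_acc),
                   confusion = conf, spec = spec, seed = seed, k = k),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s/%s, %d-fold: mean accuracy %.3f (folds %s)\n",
              x$spec$family, x$spec$variant, x$k, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = " ")))
  invisible(x)
}

#' Cross-validated benchmark grid over feature sets and classifiers
#'
#' Runs every classifier spec on every named feature table, optionally also
#' on its ANOVA-reduced variant, with one deterministic derived seed per
#' grid cell. Cells whose fit fails (e.g. quadratic discriminant on a
#' rank-deficient wide table) or whose reduced table is empty are recorded
#' with NA accuracy rather than aborting the grid.
#'
#' @param tables named list of `feature_table`s.
#' @param specs list of [classifier_spec()]s (default: the full catalog).
#' @param k folds (default 5).
#' @param seed master seed; cell seeds are derived from it.
#' @param reduced also run each table's ANOVA-reduced variant (default TRUE).
#' @param alpha significance level for the reduction.
#' @return A long data.frame with one row per (feature set, reduced flag,
#'   family, variant, fold) plus the mean rows' `mean_accuracy`; the
#'   `cv_results` attribute holds the full `cv_result` objects.
#' @export
run_grid <- function(tables, specs = NULL, k = 5L, seed = 1L,
                     reduced = TRUE, alpha = 0.05) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (is.null(specs)) {
    ct <- classifier_catalog()
    specs <- lapply(seq_len(nrow(ct)),
                    function(i) classifier_spec(ct$family[i], ct$variant[i]))
  }
  jobs <- list()
  for (nm in names(tables)) {
    jobs[[length(jobs) + 1L]] <- list(name = nm, table = tables[[nm]],
                                      reduced = FALSE)
    if (reduced) {
      tab <- tables[[nm]]
      red <- tryCatch({
        mask <- select_features(tab, alpha = alpha,
                                classes = sort(unique(tab$label)))
        reduce_table(tab, mask)
      }, error = function(e) NULL)
      jobs[[length(jobs) + 1L]] <- list(name = nm, table = red,
                                        reduced = TRUE)
    }
  }
  rows <- list()
  results <- list()
  cell <- 0L
  for (job in jobs) {
    for (spec in specs) {
      cell <- cell + 1L
      cell_seed <- (as.integer(seed) %% 100000L) * 20011L + cell * 7L
      res <- if (is.null(job$table) || ncol(job$table$features) == 0L ||
                 isTRUE(attr(job$table, "empty"))) NULL
             else tryCatch(crossval(job$table, spec, k = k, seed = cell_seed),
                           error = function(e) NULL)
      acc <- if (is.null(res)) rep(NA_real_, k) else res$fold_accuracies
      rows[[cell]] <- data.frame(
        feature_set = job$name, reduced = job$reduced,
        family = spec$family, variant = spec$variant,
        fold = seq_len(k), accuracy = acc,
        mean_accuracy = if (is.null(res)) NA_real_ else res$mean_accuracy,
        seed = cell_seed, stringsAsFactors = FALSE)
      results[[cell]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cv_results") <- results
  out
}

#' Best-variant-per-family summary of a benchmark grid
#'
#' Collapses a [run_grid()] result to one row per (feature set, reduced
#' flag, family), keeping the variant with the highest mean accuracy — the
#' convention used when a single number is reported per family. Families
#' with no successful variant get NA.
#'
#' @param grid a [run_grid()] result.
#' @return data.frame with `feature_set`, `reduced`, `family`,
#'   `best_variant`, `mean_accuracy`.
#' @export
summarize_grid <- function(grid) {
  cells <- unique(grid[, c("feature_set", "reduced", "family", "variant",
                           "mean_accuracy")])
  key <- interaction(cells$feature_set, cells$reduced, cells$family,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(cells, key), function(d) {
    if (all(is.na(d$mean_accuracy))) {
      d1 <- d[1, ]
      d1$variant <- NA_character_
      d1
    } else d[which.max(d$mean_accuracy), ]
  }))
  names(out)[names(out) == "variant"] <- "best_variant"
  rownames(out) <- NULL
  out[order(out$feature_set, out$reduced, out$family), ]
}
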