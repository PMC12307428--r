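#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Defaults mirror the target
#' analysis: alpha 0.05, 5 folds, 8 subjects with 100 segments per class.
#' Tests and examples scale `n_subjects`/`n_per_class`/`classifiers` down.
#'
#' @param scope "subject_independent" (pool all subjects into one analysis)
#'   or "subject_dependent" (per-subject analyses plus a count-mode map).
#' @param domains feature domains to extract.
#' @param alpha ANOVA significance level, in (0, 1).
#' @param k cross-validation folds (>= 2).
#' @param seed master seed.
#' @param n_subjects,n_per_class synthetic cohort size.
#' @param effect an [effect_config()].
#' @param classifiers data.frame of family/variant rows to benchmark
#'   (default: the full [classifier_catalog()]).
#' @param out output directory for [run_pipeline()] artifacts.
#' @return A `run_config`.
#' @export
run_config <- function(scope = c("subject_independent", "subject_dependent"),
                       domains = c("TD", "FD", "TF", "ND"),
                       alpha = 0.05, k = 5L, seed = 1L,
                       n_subjects = 8L, n_per_class = 100L,
                       effect = effect_config(),
                       classifiers = classifier_catalog(),
                       out = tempfile("fingereeg_run_")) {
  scope <- match.arg(scope)
  stopifnot(alpha > 0, alpha < 1, k >= 2L, n_subjects >= 1L,
            n_per_class >= 2L, all(domains %in% c("TD", "FD", "TF", "ND")))
  structure(list(scope = scope, domains = domains, alpha = alpha,
                 k = as.integer(k), seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 n_per_class = as.integer(n_per_class),
                 effect = effect, classifiers = classifiers, out = out),
            class = "run_config")
}

.grid_specs <- function(classifiers) {
  lapply(seq_len(nrow(classifiers)), function(i)
    classifier_spec(classifiers$family[i], classifiers$variant[i]))
}

#' Run the full pipeline: generate, extract, select, map, classify, report
#'
#' Executes both analysis branches — classifiers on the full feature sets
#' and on the ANOVA-reduced ones — and writes every artifact under
#' `config$out`: feature tables (full and reduced) as CSV, selection masks
#' and distribution maps as JSON (binary maps for the pooled
#' subject-independent scope, 0..n_subjects count maps for the
#' subject-dependent scope), the long results table as CSV, and a
#' `manifest.json` with seeds, shapes, versions and per-stage timings.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = 1L,
                   package_version = as.character(utils::packageVersion("fingereeg")),
                   r_version = R.version.string,
                   scope = config$scope, alpha = config$alpha, k = config$k,
                   seed = config$seed, n_subjects = config$n_subjects,
                   n_per_class = config$n_per_class,
                   domains = config$domains, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0, ...) {
    info <- list(seconds = round(tic() - t0, 2), ...)
    manifest$stages[[name]] <<- info
    message(sprintf("[%s] %.1fs %s", name, info$seconds,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  t0 <- tic()
  dataset <- generate_dataset(config$n_subjects, config$n_per_class,
                              config$effect, seed = config$seed)
  log_stage("synth", t0, subjects = length(dataset),
            segments = sum(vapply(dataset, function(d) length(d$segments), 0L)))

  t0 <- tic()
  per_subject <- lapply(dataset, build_feature_table, sets = config$domains)
  pooled <- new_feature_table(
    do.call(rbind, lapply(per_subject, `[[`, "features")),
    unlist(lapply(per_subject, `[[`, "subject")),
    unlist(lapply(per_subject, `[[`, "label")),
    config$domains)
  write_feature_table(pooled, file.path(config$out, "features_pooled.csv"))
  log_stage("extract", t0, features = ncol(pooled$features),
            segments = nrow(pooled$features))

  specs <- .grid_specs(config$classifiers)
  if (config$scope == "subject_independent") {
    t0 <- tic()
    mask <- select_features(pooled, alpha = config$alpha)
    write_mask(mask, file.path(config$out, "mask_pooled.json"))
    reduced <- reduce_table(pooled, mask)
    write_feature_table(reduced, file.path(config$out, "features_reduced.csv"))
    maps <- lapply(config$domains, function(d)
      distribution_map(subset_mask(mask, d), d))
    names(maps) <- config$domains
    for (d in config$domains) {
      write_map(maps[[d]], file.path(config$out, paste0("map_", d, ".json")))
      map_to_csv(maps[[d]], file.path(config$out, paste0("map_", d, ".csv")))
    }
    log_stage("select", t0, selected = sum(mask$significant))

    t0 <- tic()
    set_name <- paste(config$domains, collapse = "+")
    grid <- run_grid(stats::setNames(list(pooled), set_name), specs,
                     k = config$k, seed = config$seed,
                     reduced = TRUE, alpha = config$alpha)
    write.csv(grid, file.path(config$out, "results.csv"), row.names = FALSE)
    write.csv(summarize_grid(grid),
              file.path(config$out, "results_by_family.csv"),
              row.names = FALSE)
    log_stage("classify", t0, cells = nrow(grid) / config$k)
    manifest$selected <- sum(mask$significant)
    manifest$map_grand_totals <- lapply(maps, `[[`, "grand_total")
  } else {
    t0 <- tic()
    masks <- lapply(per_subject, select_features, alpha = config$alpha)
    maps <- lapply(config$domains, function(d)
      distribution_map(lapply(masks, subset_mask, domain = d), d))
    names(maps) <- config$domains
    for (d in config$domains) {
      write_map(maps[[d]], file.path(config$out, paste0("map_", d, "_count.json")))
      map_to_csv(maps[[d]], file.path(config$out, paste0("map_", d, "_count.csv")))
    }
    log_stage("select", t0,
              selected = sum(vapply(masks, function(m) sum(m$significant), 0L)))

    t0 <- tic()
    grids <- lapply(names(per_subject), function(s) {
      g <- run_grid(stats::setNames(list(per_subject[[s]]),
                                    paste(config$domains, collapse = "+")),
                    specs, k = config$k,
                    seed = config$seed + match(s, names(per_subject)),
                    reduced = TRUE, alpha = config$alpha)
      g$subject <- s
      g
    })
    grid <- do.call(rbind, grids)
    write.csv(grid, file.path(config$out, "results.csv"), row.names = FALSE)
    log_stage("classify", t0, cells = nrow(grid) / config$k)
    manifest$map_grand_totals <- lapply(maps, `[[`, "grand_total")
  }

  manifest$feature_counts <- list(TD = 456L, FD = 285L, TF = 285L, ND = 76L)
  manifest$n_features <- ncol(pooled$features)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write the tiny deterministic fixture collection used by the test suite
#'
#' One subject, four segments per class (24 segments), written with
#' [write_collection()] plus its 456-column time-domain feature table.
#' Regeneration with the same seed is byte-identical.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
make_fixtures <- function(seed = 42L, dir = tempfile("fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coll <- generate_dataset(1, 4, effect_config(), seed = seed)[[1]]
  paths <- write_collection(coll, file.path(dir, "fixture"))
  tab <- build_feature_table(coll, sets = "TD")
  td_path <- file.path(dir, "fixture_td.csv")
  write_feature_table(tab, td_path)
  invisible(c(paths, td_path))
}
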