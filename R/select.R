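#' Assemble a feature table from a segment collection
#'
#' Extracts the requested domains for every segment and concatenates them in
#' the fixed order TD, FD, TF, ND. Canonical column counts: TD 456, FD 285,
#' TF 285, ND 76; TD+FD+TF 1026; all four 1102.
#'
#' @param collection a `segment_collection` (or a plain list of
#'   `eeg_segment`).
#' @param sets character subset of c("TD", "FD", "TF", "ND").
#' @param ... forwarded to the per-domain extractors.
#' @return A `feature_table`: list with `features` (numeric matrix,
#'   segments x features, feature-id column names), `subject`, `label`
#'   vectors and `sets`.
#' @export
#' @examples
#' ds <- generate_dataset(1, 2, seed = 1)
#' tab <- build_feature_table(ds[[1]], sets = "ND")
#' dim(tab$features)  # 12 x 76
build_feature_table <- function(collection, sets = c("TD", "FD", "TF", "ND"),
                                ...) {
  segments <- if (inherits(collection, "segment_collection"))
    collection$segments else collection
  if (!length(segments)) stop("collection is empty")
  known <- c("TD", "FD", "TF", "ND")
  if (length(bad <- setdiff(sets, known)))
    stop("unknown feature set name(s): ", paste(bad, collapse = ", "))
  sets <- known[known %in% sets]          # enforce canonical order
  extractors <- list(TD = extract_td, FD = extract_fd,
                     TF = extract_tf, ND = extract_nd)
  rows <- lapply(segments, function(seg) {
    unlist(lapply(sets, function(s) extractors[[s]](seg, ...)),
           use.names = TRUE)
  })
  feats <- do.call(rbind, rows)
  new_feature_table(
    feats,
    subject = vapply(segments, `[[`, "", "subject"),
    label = vapply(segments, `[[`, integer(1), "label"),
    sets = sets
  )
}

new_feature_table <- function(features, subject, label, sets) {
  stopifnot(is.matrix(features), nrow(features) == length(subject),
            length(subject) == length(label))
  structure(list(features = features, subject = as.character(subject),
                 label = as.integer(label), sets = sets),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d segments x %d features [%s]; %d subject(s)\n",
              nrow(x$features), ncol(x$features),
              paste(x$sets, collapse = "+"), length(unique(x$subject))))
  invisible(x)
}

#' One-way ANOVA p-value
#'
#' Classical fixed-effects one-way ANOVA F-test across k groups, computed
#' from between/within sums of squares. A degenerate input with zero total
#' variance returns p = 1 (such a feature can never be selected).
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return p-value in [0, 1].
#' @export
#' @examples
#' anova_pvalue(list(rnorm(10), rnorm(10) + 5))  # tiny p
anova_pvalue <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  .anova_pvalues(matrix(y, ncol = 1), g)[1]
}

# vectorized one-way ANOVA over the columns of X, grouped by g
.anova_pvalues <- function(X, g) {
  g <- as.integer(factor(g))
  k <- max(g)
  n <- nrow(X)
  counts <- tabulate(g, k)
  gsum <- rowsum(X, g, reorder = TRUE)
  gmean <- gsum / counts
  grand <- colSums(X) / n
  ssb <- colSums(gmean^2 * counts) - n * grand^2
  sst <- colSums(X^2) - n * grand^2
  ssw <- sst - ssb
  df1 <- k - 1L
  df2 <- n - k
  # guard tiny negative rounding and degenerate zero-variance columns
  ssb <- pmax(ssb, 0)
  ssw <- pmax(ssw, 0)
  p <- numeric(ncol(X))
  degenerate <- sst <= .Machine$double.eps * pmax(1, colSums(X^2))
  perfect <- !degenerate & ssw <= .Machine$double.eps * sst
  normal <- !degenerate & !perfect
  Fstat <- (ssb[normal] / df1) / (ssw[normal] / df2)
  p[normal] <- pf(Fstat, df1, df2, lower.tail = FALSE)
  p[degenerate] <- 1
  p[perfect] <- 0
  p
}

#' ANOVA significance screening of a feature table
#'
#' One p-value per feature column from a one-way ANOVA across the class
#' labels; a feature is significant when p < alpha (raw p-values by default,
#' matching the analysis this package implements; Benjamini-Hochberg is
#' available via `adjust`).
#'
#' @param table a `feature_table`.
#' @param alpha significance level in [0, 1) (default 0.05).
#' @param classes class labels that must all be present (default 1:6).
#' @param adjust "none" (default) or "BH".
#' @return A `selection_mask`: data.frame with `id`, `p_value`,
#'   `significant`, plus attributes `alpha` and `adjust`.
#' @export
select_features <- function(table, alpha = 0.05, classes = 1:6,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"), alpha >= 0, alpha < 1)
  adjust <- match.arg(adjust)
  present <- unique(table$label)
  if (length(miss <- setdiff(classes, present)))
    stop("class(es) absent from table: ", paste(miss, collapse = ", "))
  if (any(table(table$label) < 2L)) stop("every class needs >= 2 segments")
  p <- .anova_pvalues(table$features, table$label)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  mask <- data.frame(id = colnames(table$features), p_value = p,
                     significant = p < alpha, stringsAsFactors = FALSE)
  attr(mask, "alpha") <- alpha
  attr(mask, "adjust") <- adjust
  class(mask) <- c("selection_mask", "data.frame")
  mask
}

#' Reduce a feature table to its significant columns
#'
#' @param table a `feature_table`.
#' @param mask a `selection_mask` whose ids match the table's columns.
#' @return A `feature_table` with only the significant columns (order
#'   preserved). When no column survives, an empty table is returned with
#'   attribute `empty = TRUE`; the classification stage refuses such tables.
#' @export
reduce_table <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"), inherits(mask, "selection_mask"))
  if (!identical(mask$id, colnames(table$features)))
    stop("mask does not match table columns")
  keep <- mask$significant
  out <- new_feature_table(table$features[, keep, drop = FALSE],
                           table$subject, table$label, table$sets)
  if (!any(keep)) attr(out, "empty") <- TRUE
  out
}

# the per-domain (codes x 19) grid skeleton
.domain_codes <- function(domain) {
  switch(domain,
         TD = td_catalog()$code,
         FD = paste0("FD", 1:15),
         TF = paste0("TF", 1:15),
         ND = paste0("ND", 1:4),
         stop("unknown feature domain: ", domain))
}

#' Restrict a selection mask to one feature domain
#'
#' @param mask a `selection_mask`.
#' @param domain one of "TD", "FD", "TF", "ND".
#' @return A `selection_mask` containing only that domain's columns.
#' @export
subset_mask <- function(mask, domain) {
  stopifnot(inherits(mask, "selection_mask"))
  keep <- parse_feature_ids(mask$id)$domain == domain
  if (!any(keep)) stop("mask contains no ", domain, " features")
  out <- mask[keep, , drop = FALSE]
  attr(out, "alpha") <- attr(mask, "alpha")
  attr(out, "adjust") <- attr(mask, "adjust")
  class(out) <- c("selection_mask", "data.frame")
  rownames(out) <- NULL
  out
}

#' Channel-by-feature significance distribution map
#'
#' Summarizes which (feature type, channel) cells were selected. With a
#' single mask the map is binary (cell = 1 iff that feature was
#' significant); with a list of per-subject masks each cell counts the
#' subjects (0..n) for which it was selected. Row, column and grand totals
#' mirror the "Total" margins of the published map layout.
#'
#' @param masks one `selection_mask`, or a list of them (count mode).
#' @param domain one of "TD", "FD", "TF", "ND".
#' @return A `distribution_map`: list with `grid` (types x 19 channels
#'   integer matrix), `mode`, `row_totals`, `col_totals`, `grand_total`,
#'   `domain`, `n_masks`.
#' @export
distribution_map <- function(masks, domain) {
  codes <- .domain_codes(domain)
  if (inherits(masks, "selection_mask")) {
    mode <- "binary"
    masks <- list(masks)
  } else {
    stopifnot(is.list(masks), all(vapply(masks, inherits, logical(1),
                                         "selection_mask")))
    mode <- "count"
  }
  grid <- matrix(0L, nrow = length(codes), ncol = N_CHANNELS,
                 dimnames = list(codes, paste0("ch", seq_len(N_CHANNELS))))
  for (m in masks) {
    info <- parse_feature_ids(m$id)
    if (any(info$domain != domain))
      stop("mask mixes feature domains; use subset_mask() first")
    idx <- cbind(match(info$type_code, codes), info$channel)
    if (anyNA(idx) || nrow(idx) != length(codes) * N_CHANNELS)
      stop("mask ids do not cover the ", domain, " grid exactly")
    grid[idx] <- grid[idx] + as.integer(m$significant)
  }
  structure(list(grid = grid, mode = mode, domain = domain,
                 n_masks = length(masks),
                 row_totals = rowSums(grid), col_totals = colSums(grid),
                 grand_total = sum(grid)),
            class = "distribution_map")
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf("<distribution_map> %s, %s mode (%d mask%s): %d x %d grid, grand total %d\n",
              x$domain, x$mode, x$n_masks, if (x$n_masks > 1) "s" else "",
              nrow(x$grid), ncol(x$grid), x$grand_total))
  invisible(x)
}

# ---- plain-text serialization ------------------------------------------

#' Read and write pipeline artifacts as CSV/JSON
#'
#' `write_feature_table`/`read_feature_table` use one CSV with a `subject`
#' and a `label` column plus one column per feature id. Selection masks and
#' distribution maps serialize to JSON with a `schema_version` field; maps
#' can additionally be exported as a CSV grid shaped like the published
#' tables (`map_to_csv`).
#'
#' @param table,mask,map the object to write.
#' @param path destination/source file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject = table$subject, label = table$label,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$features, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("subject", "label") %in% names(df)))
    stop("feature table CSV must have subject and label columns")
  feats <- as.matrix(df[, setdiff(names(df), c("subject", "label")),
                        drop = FALSE])
  sets <- unique(parse_feature_ids(colnames(feats))$domain)
  new_feature_table(feats, df$subject, df$label, sets)
}

#' @rdname write_feature_table
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "selection_mask"))
  jsonlite::write_json(
    list(schema_version = 1L, alpha = attr(mask, "alpha"),
         adjust = attr(mask, "adjust"),
         id = mask$id, p_value = mask$p_value,
         significant = mask$significant),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_mask <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- data.frame(id = x$id, p_value = x$p_value,
                     significant = x$significant, stringsAsFactors = FALSE)
  attr(mask, "alpha") <- x$alpha
  attr(mask, "adjust") <- x$adjust
  class(mask) <- c("selection_mask", "data.frame")
  mask
}

#' @rdname write_feature_table
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "distribution_map"))
  jsonlite::write_json(
    list(schema_version = 1L, domain = map$domain, mode = map$mode,
         n_masks = map$n_masks, codes = rownames(map$grid),
         grid = unname(apply(map$grid, 1, as.integer, simplify = FALSE)),
         row_totals = unname(map$row_totals),
         col_totals = unname(map$col_totals),
         grand_total = map$grand_total),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
map_to_csv <- function(map, path) {
  stopifnot(inherits(map, "distribution_map"))
  df <- as.data.frame(map$grid)
  df <- cbind(Features = rownames(map$grid), df, Total = map$row_totals)
  df <- rbind(df, c(Features = "Total", as.list(map$col_totals),
                    Total = map$grand_total))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
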