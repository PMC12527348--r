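#' Pivot molecule counts into a feature-by-sample matrix
#'
#' @param counts A [count_molecules()] result computed with
#'   `grouping = "sample_name"`.
#' @param statistic `"count"`, `"avg_polyA_length"` or
#'   `"median_polyA_length"` — which cell statistic to spread.
#' @return A `feature_matrix` tibble: `feature_id` plus one column per
#'   sample; cells are missing where a feature has no reads in a sample.
#'   Attributes `statistic` and `level` record provenance.
#' @export
build_feature_matrix <- function(counts,
                                 statistic = c("count", "avg_polyA_length",
                                               "median_polyA_length")) {
  if (is.character(statistic) && length(statistic) == 1 &&
      !statistic %in% c("count", "avg_polyA_length", "median_polyA_length")) {
    stop_validation(sprintf("Unknown statistic '%s'.", statistic))
  }
  statistic <- match.arg(statistic)
  assert_data_frame(counts)
  assert_columns(counts, c("feature_id", "grouping_value", statistic),
                 arg = "counts")
  grouping <- attr(counts, "grouping")
  if (!is.null(grouping) && grouping != "sample_name") {
    stop_validation(
      "`counts` must be grouped by sample_name (rerun count_molecules(..., grouping = \"sample_name\"))."
    )
  }
  out <- counts |>
    select(dplyr::all_of(c("feature_id", "grouping_value", statistic))) |>
    tidyr::pivot_wider(names_from = "grouping_value",
                       values_from = dplyr::all_of(statistic)) |>
    arrange(.data$feature_id)
  attr(out, "statistic") <- statistic
  attr(out, "level") <- attr(counts, "level")
  class(out) <- c("feature_matrix", class(as_tibble(out)))
  out
}

#' Principal component analysis of samples on a feature matrix
#'
#' Samples are the observations and features the variables. Features with a
#' missing cell in any sample are dropped (and counted) rather than imputed:
#' fabricating a tail length of zero would distort a length metric. Columns
#' are centred but not scaled before the singular value decomposition
#' ([stats::prcomp()]). For a reproducible orientation, each component is
#' flipped if needed so that its largest-magnitude loading is positive.
#'
#' @param matrix A [build_feature_matrix()] result.
#' @param samples The samples table (maps `sample_name` to grouping values).
#' @param grouping_factor Column of `samples` used to label score rows
#'   (default `"group"`).
#' @return A `polya_pca` object: list with `scores` (tibble: `sample_name`,
#'   grouping label, `PC1..PCm`), `loadings`, `var_explained`,
#'   `n_features_used`, `n_features_dropped`.
#' @export
run_pca <- function(matrix, samples, grouping_factor = "group") {
  assert_data_frame(matrix)
  assert_columns(matrix, "feature_id", arg = "matrix")
  assert_data_frame(samples)
  assert_columns(samples, c("sample_name", grouping_factor), arg = "samples")
  sample_cols <- setdiff(names(matrix), "feature_id")
  if (length(sample_cols) < 2) stop_validation("Need at least 2 samples for PCA.")
  m <- as.matrix(as_tibble(matrix)[, sample_cols])
  rownames(m) <- matrix$feature_id
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (sum(complete) < 2) {
    stop_validation("Fewer than 2 features are observed in every sample.")
  }
  if (n_dropped > 0) {
    inform(sprintf("run_pca: dropped %d feature(s) with missing cells.",
                   n_dropped))
  }
  x <- t(m[complete, , drop = FALSE])  # samples x features
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| per component is positive
  for (j in seq_len(ncol(pc$rotation))) {
    peak <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[peak, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, rownames = "sample_name")
  lab <- samples[, c("sample_name", grouping_factor)]
  scores <- left_join(scores, as_tibble(lab), by = "sample_name") |>
    dplyr::relocate(dplyr::all_of(grouping_factor), .after = "sample_name")
  structure(list(
    scores = scores,
    loadings = pc$rotation,
    center = pc$center,
    var_explained = var_explained,
    grouping_factor = grouping_factor,
    n_features_used = sum(complete),
    n_features_dropped = n_dropped
  ), class = "polya_pca")
}

#' @export
print.polya_pca <- function(x, ...) {
  cat(sprintf("PCA of %d sample(s) on %d complete feature(s) (%d dropped)\n",
              nrow(x$scores), x$n_features_used, x$n_features_dropped))
  cat("Variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.polya_pca <- function(x, ...) x$scores

#' @export
glance.polya_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_features_used = x$n_features_used,
    n_features_dropped = x$n_features_dropped,
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_
  )
}

#' Bin tail lengths into fixed-width windows
#'
#' Tiles the length axis into closed integer windows of `frame` nucleotides:
#' frame 10 gives 1-10, 11-20, ... and a length equal to a boundary falls in
#' the lower window (length 10 is in 1-10). A length L falls in window
#' `ceiling(L / frame)`. Windows run up to the tile containing the longest
#' observed tail.
#'
#' @param polya A poly(A) table.
#' @param grouping_factor Column defining the rows (`"group"` or
#'   `"sample_name"`).
#' @param frame Window width in nucleotides (>= 1).
#' @param mode `"base"` for raw counts (rows sum to the number of reads per
#'   grouping value) or `"normalized"` for row percentages (rows sum to 100).
#' @return A `binned_matrix` tibble: `grouping_value` plus one column per
#'   window labelled `"lo-hi"`. Attributes `frame` and `mode`.
#' @export
bin_tail_lengths <- function(polya, grouping_factor = "group", frame = 10,
                             mode = c("base", "normalized")) {
  mode <- match.arg(mode)
  assert_polya_table(polya)
  assert_columns(polya, grouping_factor, arg = "polya")
  if (!is.numeric(frame) || length(frame) != 1 || frame < 1 ||
      frame != round(frame)) {
    stop_validation("`frame` must be a single integer >= 1.")
  }
  if (nrow(polya) == 0) stop_validation("`polya` has no rows.")
  win <- ceiling(polya$polyA_length / frame)
  n_win <- max(win)
  labels <- paste0((seq_len(n_win) - 1) * frame + 1, "-",
                   seq_len(n_win) * frame)
  rows <- sort(unique(polya[[grouping_factor]]))
  tab <- table(factor(polya[[grouping_factor]], levels = rows),
               factor(win, levels = seq_len(n_win)))
  m <- matrix(as.numeric(tab), nrow = length(rows),
              dimnames = list(rows, labels))
  if (mode == "normalized") {
    m <- sweep(m, 1, rowSums(m), "/") * 100
  }
  out <- as_tibble(m, rownames = "grouping_value")
  attr(out, "frame") <- frame
  attr(out, "mode") <- mode
  attr(out, "grouping_factor") <- grouping_factor
  class(out) <- c("binned_matrix", class(as_tibble(out)))
  out
}

#' Hierarchically cluster the rows of a binned matrix
#'
#' Agglomerative clustering (complete linkage) on Euclidean distances
#' between the row profiles. Rows are ordered by label before clustering so
#' that distance ties break deterministically.
#'
#' @param binned A [bin_tail_lengths()] result (>= 2 rows).
#' @return An [stats::hclust()] object whose labels are the grouping values.
#' @seealso [write_newick()] to export the dendrogram.
#' @export
cluster_groups <- function(binned) {
  assert_data_frame(binned)
  assert_columns(binned, "grouping_value", arg = "binned")
  if (nrow(binned) < 2) {
    stop_validation("Need at least 2 rows to cluster.")
  }
  binned <- arrange(as_tibble(binned), .data$grouping_value)
  m <- as.matrix(binned[, setdiff(names(binned), "grouping_value")])
  rownames(m) <- binned$grouping_value
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' Write a dendrogram in Newick format
#'
#' @param hc An [stats::hclust()] object (e.g. from [cluster_groups()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  if (!inherits(hc, "hclust")) stop_validation("`hc` must be an hclust object.")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
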