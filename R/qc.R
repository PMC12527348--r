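#' Classify reads by how many transcripts they were assigned to
#'
#' A read aligned once is `unique`, twice `duplicated`, three or more times
#' `multiple`. Classification is per sample: the same read id in two samples
#' is two different molecules.
#'
#' @param polya A poly(A) table.
#' @return An object of class `duplication_summary`: a list with `counts`
#'   (tibble `class`, `n_reads`) and `reads` (tibble `sample_name`,
#'   `read_id`, `n_records`, `class`). Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
classify_read_assignments <- function(polya) {
  assert_polya_table(polya)
  if (nrow(polya) == 0) stop_validation("`polya` has no rows.")
  reads <- polya |>
    dplyr::count(.data$sample_name, .data$read_id, name = "n_records") |>
    mutate(class = dplyr::case_when(
      .data$n_records == 1 ~ "unique",
      .data$n_records == 2 ~ "duplicated",
      TRUE ~ "multiple"
    ))
  counts <- tibble(class = c("unique", "duplicated", "multiple")) |>
    left_join(dplyr::count(reads, .data$class, name = "n_reads"), by = "class") |>
    mutate(n_reads = tidyr::replace_na(.data$n_reads, 0L))
  structure(list(counts = counts, reads = reads),
            class = "duplication_summary")
}

#' @export
tidy.duplication_summary <- function(x, ...) x$reads

#' @export
glance.duplication_summary <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "class", values_from = "n_reads")
}

#' @export
print.duplication_summary <- function(x, ...) {
  cat("Read-to-transcript assignment summary\n")
  print(x$counts)
  invisible(x)
}

#' Remove within-gene duplicate tail records
#'
#' A read multi-assigned to several transcripts of the same gene contributes
#' the same molecule (and hence the same tail length) more than once to that
#' gene, which skews gene-level statistics. Among records sharing
#' (`sample_name`, `read_id`, `gene_id`, `polyA_length`) exactly one is kept
#' (the first in input order). Records differing in gene or length are all
#' kept, as are records with a missing `gene_id` (the rule is defined within
#' a gene). Transcript-level analyses typically keep the duplicates.
#'
#' @param polya A poly(A) table with a `gene_id` column.
#' @return The deduplicated table; attribute `n_removed` (also messaged)
#'   counts dropped rows.
#' @export
drop_gene_level_duplicates <- function(polya) {
  assert_polya_table(polya, require_gene = TRUE)
  key <- paste(polya$sample_name, polya$read_id, polya$gene_id,
               polya$polyA_length, sep = "\r")
  drop <- !is.na(polya$gene_id) & duplicated(key)
  out <- as_tibble(polya)[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  inform(sprintf("Removed %d within-gene duplicate record(s).", sum(drop)))
  out
}

#' Count molecules and summarise tail lengths per feature
#'
#' Counts records (molecules) per transcript or gene within each grouping
#' value, together with the mean and median tail length of that cell.
#'
#' @param polya A poly(A) table.
#' @param level `"transcript_id"` or `"gene_id"` — the feature column.
#' @param grouping `"group"` or `"sample_name"` — the column whose values
#'   define the cells.
#' @return A tibble with columns `feature_id`, `grouping_value`, `count`,
#'   `avg_polyA_length`, `median_polyA_length`. Attributes `level` and
#'   `grouping` record the choices; `n_excluded` counts records dropped for a
#'   missing feature id.
#' @export
count_molecules <- function(polya, level = c("transcript_id", "gene_id"),
                            grouping = c("group", "sample_name")) {
  level <- match.arg(level)
  grouping <- match.arg(grouping)
  assert_polya_table(polya, require_gene = level == "gene_id")
  n_excluded <- sum(is.na(polya[[level]]))
  if (n_excluded > 0) {
    inform(sprintf("count_molecules: excluded %d record(s) with missing %s.",
                   n_excluded, level))
  }
  out <- polya |>
    filter(!is.na(.data[[level]])) |>
    group_by(feature_id = .data[[level]], grouping_value = .data[[grouping]]) |>
    summarise(
      count = dplyr::n(),
      avg_polyA_length = mean(.data$polyA_length),
      median_polyA_length = median(.data$polyA_length),
      .groups = "drop"
    )
  attr(out, "level") <- level
  attr(out, "grouping") <- grouping
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Drop features with too few poly(A) tails
#'
#' Features (transcripts or genes) supported by fewer than `min_tails`
#' records are removed entirely. With `scope = "per_group"` (default) a
#' feature must reach the threshold in every compared group; with
#' `scope = "total"` the overall count is used. The default threshold of 10
#' is the usual minimum for gene-level differential polyadenylation calls.
#'
#' @param polya A poly(A) table.
#' @param level `"transcript_id"` or `"gene_id"`.
#' @param min_tails Minimum number of tails (records) required; >= 1.
#' @param scope `"per_group"` or `"total"`.
#' @param groups Optional character vector restricting which groups must
#'   satisfy the per-group threshold (default: all groups present).
#' @return The filtered table; attributes `n_features_removed` and
#'   `n_records_removed` report the effect.
#' @export
filter_min_tails <- function(polya, level = c("transcript_id", "gene_id"),
                             min_tails = 10, scope = c("per_group", "total"),
                             groups = NULL) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  assert_polya_table(polya, require_gene = level == "gene_id")
  if (!is.numeric(min_tails) || length(min_tails) != 1 || min_tails < 1) {
    stop_validation("`min_tails` must be a single integer >= 1.")
  }
  groups <- groups %||% unique(polya$group)
  usable <- polya[!is.na(polya[[level]]), , drop = FALSE]
  n_na <- nrow(polya) - nrow(usable)
  if (n_na > 0) {
    inform(sprintf("filter_min_tails: dropped %d record(s) with missing %s.",
                   n_na, level))
  }
  if (scope == "per_group") {
    tallies <- usable |>
      filter(.data$group %in% groups) |>
      dplyr::count(feature_id = .data[[level]], .data$group) |>
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         values_fill = 0L)
    for (g in setdiff(groups, names(tallies))) tallies[[g]] <- 0L
    cnt <- as.matrix(tallies[, groups, drop = FALSE])
    keep_ids <- tallies$feature_id[rowSums(cnt >= min_tails) == length(groups)]
  } else {
    keep_ids <- usable |>
      dplyr::count(feature_id = .data[[level]]) |>
      filter(.data$n >= min_tails) |>
      pull(.data$feature_id)
  }
  out <- usable[usable[[level]] %in% keep_ids, , drop = FALSE]
  attr(out, "n_features_removed") <-
    dplyr::n_distinct(usable[[level]]) - length(keep_ids)
  attr(out, "n_records_removed") <- nrow(polya) - nrow(out)
  out
}
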