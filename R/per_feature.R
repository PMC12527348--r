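# Run the adaptive (or forced) two-group machinery on one feature's values.
fit_one_two_group <- function(control, treated, mode, alpha_assumption) {
  if (mode == "wilcoxon_only") {
    test_id <- "wilcoxon"
  } else {
    report <- assess_groups(list(control = control, treated = treated))
    test_id <- select_test(report, k = 2, alpha_assumption = alpha_assumption)
  }
  ht <- tryCatch(
    run_two_group_test(control, treated, test_id = test_id),
    polytail_degenerate_error = function(e) {
      # zero variance everywhere: t undefined, fall through to rank test
      run_two_group_test(control, treated, test_id = "wilcoxon")
    }
  )
  ht
}

#' Per-feature differential polyadenylation between two groups
#'
#' For every transcript or gene, compares tail lengths between a control and
#' a treated group. `mode = "wilcoxon_only"` always uses the Wilcoxon
#' rank-sum test; `mode = "adaptive"` checks normality and variance
#' homogeneity per feature and selects Student's t, Welch's t or Wilcoxon
#' (see [select_test()]). Cohen's d and the log2 fold change of mean tail
#' length (treated over control) are attached, p-values are adjusted across
#' tested features, and each feature receives a differential-polyadenylation
#' call via [call_dpgs()].
#'
#' @param polya A poly(A) table (with `gene_id` when `level = "gene_id"`).
#' @param level `"transcript_id"` or `"gene_id"`.
#' @param control_group,treated_group Group labels (must exist in
#'   `polya$group`).
#' @param mode `"adaptive"` or `"wilcoxon_only"`.
#' @param adjust_method Multiple-testing correction (see
#'   [adjust_pvalues()]); default `"BH"`.
#' @param min_n Minimum observations per group for a feature to be tested;
#'   features below it get `dpg_call = "not_tested"` and a missing p.
#' @param alpha Significance level for the DPG call (adjusted p strictly
#'   below `alpha`); default 0.05.
#' @param alpha_assumption Significance level of the per-feature assumption
#'   checks in adaptive mode; default 0.05.
#'
#' @return A `feature_stats` tibble with columns `feature_id`, `n_control`,
#'   `n_treated`, `mean_control`, `mean_treated`, `test_id`, `statistic`,
#'   `p_value`, `padj`, `cohens_d`, `log2fc`, `dpg_call`. Metadata (mode,
#'   adjustment, alpha, labels, level) is stored in attributes and shown by
#'   [glance()].
#' @export
per_feature_two_group <- function(polya, level = c("gene_id", "transcript_id"),
                                  control_group, treated_group,
                                  mode = c("adaptive", "wilcoxon_only"),
                                  adjust_method = "BH", min_n = 1,
                                  alpha = 0.05, alpha_assumption = 0.05) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  assert_polya_table(polya, require_gene = level == "gene_id")
  present <- unique(polya$group)
  for (lab in c(control_group, treated_group)) {
    if (!lab %in% present) {
      stop_validation(sprintf(
        "Group '%s' is not present in the table (groups: %s).",
        lab, paste(present, collapse = ", ")
      ))
    }
  }
  dat <- polya |>
    filter(.data$group %in% c(control_group, treated_group),
           !is.na(.data[[level]]))
  split_vals <- split(
    list(len = dat$polyA_length, grp = dat$group) |> as_tibble(),
    dat[[level]]
  )
  rows <- purrr::imap(split_vals, function(d, fid) {
    ctl <- d$len[d$grp == control_group]
    trt <- d$len[d$grp == treated_group]
    base <- tibble(
      feature_id = fid,
      n_control = length(ctl), n_treated = length(trt),
      mean_control = if (length(ctl)) mean(ctl) else NA_real_,
      mean_treated = if (length(trt)) mean(trt) else NA_real_
    )
    if (length(ctl) < min_n || length(trt) < min_n) {
      return(mutate(base, test_id = NA_character_, statistic = NA_real_,
                    p_value = NA_real_, cohens_d = NA_real_,
                    log2fc = NA_real_))
    }
    ht <- fit_one_two_group(ctl, trt, mode, alpha_assumption)
    d_eff <- if (length(ctl) >= 2 && length(trt) >= 2 &&
                 (stats::var(ctl) > 0 || stats::var(trt) > 0)) {
      cohens_d(ctl, trt)
    } else NA_real_
    mutate(base,
           test_id = ht$test_id, statistic = ht$statistic,
           p_value = ht$p_value, cohens_d = d_eff,
           log2fc = log2_fold_change(base$mean_control, base$mean_treated))
  })
  out <- dplyr::bind_rows(rows) |> arrange(.data$feature_id)
  out$padj <- adjust_pvalues(out$p_value, adjust_method)
  out <- new_feature_stats(out, meta = list(
    comparison = "two_group", mode = mode, adjust_method = adjust_method,
    alpha = alpha, control_group = control_group,
    treated_group = treated_group, level = level
  ))
  call_dpgs(out, alpha = alpha)
}

#' Per-feature differential polyadenylation across three or more groups
#'
#' Omnibus test per transcript or gene across all values of the grouping
#' column. `mode = "kruskal_only"` always uses the Kruskal-Wallis test;
#' `mode = "adaptive"` selects one-way ANOVA, Welch's ANOVA or
#' Kruskal-Wallis from the per-feature assumption checks. Pairwise post-hoc
#' results (Tukey HSD / Games-Howell / Dunn-Bonferroni, matching the
#' omnibus test) are attached per feature in the `posthoc` list-column and
#' can be flattened with [posthoc_table()]. No control/treated designation
#' exists, so effect-size and log2 fold-change columns are absent and
#' significant features are called `"dpg"` (direction-free).
#'
#' @inheritParams per_feature_two_group
#' @param grouping `"group"` or `"sample_name"` — the column whose >= 3
#'   values are compared.
#' @param mode `"adaptive"` or `"kruskal_only"`.
#' @return A `feature_stats` tibble with columns `feature_id`, `n_total`,
#'   one `n_<group>` column per group, `test_id`, `statistic`, `p_value`,
#'   `padj`, `dpg_call`, `posthoc` (list-column of tibbles).
#' @export
per_feature_k_group <- function(polya, level = c("gene_id", "transcript_id"),
                                grouping = c("group", "sample_name"),
                                mode = c("adaptive", "kruskal_only"),
                                adjust_method = "BH", min_n = 1,
                                alpha = 0.05, alpha_assumption = 0.05) {
  level <- match.arg(level)
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  assert_polya_table(polya, require_gene = level == "gene_id")
  labels <- sort(unique(polya[[grouping]]))
  if (length(labels) < 3) {
    stop_validation(paste0(
      "Fewer than 3 grouping values (", paste(labels, collapse = ", "),
      "); use per_feature_two_group() for two-group comparisons."
    ))
  }
  dat <- polya |> filter(!is.na(.data[[level]]))
  split_vals <- split(
    tibble(len = dat$polyA_length, grp = dat[[grouping]]),
    dat[[level]]
  )
  rows <- purrr::imap(split_vals, function(d, fid) {
    groups <- purrr::map(setNames(labels, labels),
                         function(l) d$len[d$grp == l])
    ns <- lengths(groups)
    base <- tibble(feature_id = fid, n_total = sum(ns))
    for (l in labels) base[[paste0("n_", l)]] <- ns[[l]]
    if (any(ns < min_n)) {
      return(mutate(base, test_id = NA_character_, statistic = NA_real_,
                    p_value = NA_real_, posthoc = list(NULL)))
    }
    test_id <- if (mode == "kruskal_only") {
      "kruskal_wallis"
    } else {
      select_test(assess_groups(groups), k = length(groups),
                  alpha_assumption = alpha_assumption)
    }
    ht <- run_k_group_test(groups, test_id = test_id)
    mutate(base, test_id = ht$test_id, statistic = ht$statistic,
           p_value = ht$p_value, posthoc = list(ht$posthoc))
  })
  out <- dplyr::bind_rows(rows) |> arrange(.data$feature_id)
  out$padj <- adjust_pvalues(out$p_value, adjust_method)
  out <- new_feature_stats(out, meta = list(
    comparison = "k_group", mode = mode, adjust_method = adjust_method,
    alpha = alpha, grouping = grouping, level = level,
    group_labels = labels
  ))
  call_dpgs(out, alpha = alpha)
}

new_feature_stats <- function(df, meta) {
  if (anyDuplicated(df$feature_id) > 0) {
    stop_validation("Internal error: duplicated feature_id in stats table.")
  }
  structure(df, class = c("feature_stats", class(as_tibble(df))),
            polytail_meta = meta)
}

feature_stats_meta <- function(stats) {
  attr(stats, "polytail_meta") %||% list()
}

#' Call differentially polyadenylated features
#'
#' A feature is differentially polyadenylated when its adjusted p-value is
#' strictly below `alpha`. For two-group tables the direction comes from the
#' log2 fold change: `"collapsed"` (shortened tails, log2fc < 0) or
#' `"expansion"` (lengthened tails, log2fc > 0); non-significant features
#' are `"ns"` and untested ones `"not_tested"`. k-group tables have no
#' direction, so significant features are labelled `"dpg"`.
#'
#' @param stats A `feature_stats` table with a populated `padj` column.
#' @param alpha Significance level (default 0.05; the comparison is strict).
#' @return The table with its `dpg_call` column (re)computed.
#' @export
call_dpgs <- function(stats, alpha = 0.05) {
  assert_data_frame(stats)
  assert_columns(stats, c("feature_id", "padj"), arg = "stats")
  meta <- feature_stats_meta(stats)
  meta$alpha <- alpha
  if ("log2fc" %in% names(stats)) {
    call <- dplyr::case_when(
      is.na(stats$padj) ~ "not_tested",
      stats$padj < alpha & stats$log2fc < 0 ~ "collapsed",
      stats$padj < alpha & stats$log2fc > 0 ~ "expansion",
      TRUE ~ "ns"
    )
  } else {
    call <- dplyr::case_when(
      is.na(stats$padj) ~ "not_tested",
      stats$padj < alpha ~ "dpg",
      TRUE ~ "ns"
    )
  }
  stats$dpg_call <- call
  new_feature_stats(as_tibble(stats), meta = meta)
}

#' Flatten per-feature post-hoc comparisons
#'
#' @param stats A k-group `feature_stats` table with a `posthoc` list-column.
#' @return A tibble with columns `feature_id`, `pair`, `statistic`,
#'   `p_adjusted`, `method`.
#' @export
posthoc_table <- function(stats) {
  assert_columns(stats, c("feature_id", "posthoc"), arg = "stats")
  keep <- !purrr::map_lgl(stats$posthoc, is.null)
  if (!any(keep)) {
    return(tibble(feature_id = character(), pair = character(),
                  statistic = double(), p_adjusted = double(),
                  method = character()))
  }
  purrr::map2(stats$feature_id[keep], stats$posthoc[keep],
              function(fid, ph) mutate(ph, feature_id = fid, .before = 1)) |>
    dplyr::bind_rows()
}

#' Global tail-length comparison between groups
#'
#' Pools all tail lengths per grouping value and applies the adaptive
#' decision tree to the pooled distributions — the statistic reported
#' alongside a density plot. With two grouping values this is a two-group
#' test; with three or more, an omnibus test with pairwise post-hoc
#' comparisons.
#'
#' @param polya A poly(A) table.
#' @param grouping_factor Column defining the groups (`"group"` or
#'   `"sample_name"`).
#' @param alpha_assumption Significance level of the assumption checks.
#' @return A `polya_test` object; its `assumptions` element keeps the
#'   [assess_groups()] report.
#' @export
global_group_test <- function(polya, grouping_factor = "group",
                              alpha_assumption = 0.05) {
  assert_polya_table(polya)
  assert_columns(polya, grouping_factor, arg = "polya")
  labels <- sort(unique(polya[[grouping_factor]]))
  if (length(labels) < 2) {
    stop_validation("Need at least 2 grouping values for a global test.")
  }
  groups <- purrr::map(setNames(labels, labels),
                       function(l) polya$polyA_length[polya[[grouping_factor]] == l])
  report <- assess_groups(groups)
  test_id <- select_test(report, k = length(groups),
                         alpha_assumption = alpha_assumption)
  ht <- if (length(groups) == 2) {
    tryCatch(
      run_two_group_test(groups[[1]], groups[[2]], test_id = test_id,
                         labels = labels),
      polytail_degenerate_error = function(e) {
        run_two_group_test(groups[[1]], groups[[2]], test_id = "wilcoxon",
                           labels = labels)
      }
    )
  } else {
    run_k_group_test(groups, test_id = test_id)
  }
  ht$assumptions <- report
  ht
}

#' @export
print.feature_stats <- function(x, ...) {
  meta <- feature_stats_meta(x)
  cat(sprintf(
    "Per-feature polyadenylation statistics (%s, mode = %s, adjust = %s, alpha = %g)\n",
    meta$comparison %||% "?", meta$mode %||% "?",
    meta$adjust_method %||% "?", meta$alpha %||% NA
  ))
  NextMethod()
}

#' @export
tidy.feature_stats <- function(x, ...) {
  out <- as_tibble(x)
  out[, !vapply(out, is.list, logical(1)), drop = FALSE]
}

#' @export
glance.feature_stats <- function(x, ...) {
  meta <- feature_stats_meta(x)
  tibble(
    comparison = meta$comparison %||% NA_character_,
    mode = meta$mode %||% NA_character_,
    adjust_method = meta$adjust_method %||% NA_character_,
    alpha = meta$alpha %||% NA_real_,
    level = meta$level %||% NA_character_,
    n_features = nrow(x),
    n_tested = sum(!is.na(x$padj)),
    n_dpg = sum(!x$dpg_call %in% c("ns", "not_tested"))
  )
}
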