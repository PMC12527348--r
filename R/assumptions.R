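#' Assess normality of one group of tail lengths
#'
#' Small (n < 3) or constant groups cannot be assessed and are treated as
#' non-normal downstream. Groups of 3 to 5000 observations use the
#' Shapiro-Wilk test; larger groups use the Lilliefors test (Kolmogorov-
#' Smirnov with estimated mean and sd, Dallal-Wilkinson p approximation),
#' since Shapiro-Wilk is defined only up to n = 5000.
#'
#' @param values Numeric vector of tail lengths.
#' @return A list with `method` (`"shapiro"`, `"lilliefors"` or
#'   `"not_assessable"`), `statistic`, `p` and `n`.
#' @export
assess_normality <- function(values) {
  if (!is.numeric(values)) stop_validation("`values` must be numeric.")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_validation("`values` must be finite and non-missing.")
  }
  n <- length(values)
  if (n < 3 || length(unique(values)) == 1) {
    return(list(method = "not_assessable", statistic = NA_real_,
                p = NA_real_, n = n))
  }
  if (n <= 5000) {
    ht <- stats::shapiro.test(values)
    method <- "shapiro"
  } else {
    ht <- nortest::lillie.test(values)
    method <- "lilliefors"
  }
  list(method = method, statistic = unname(ht$statistic),
       p = unname(ht$p.value), n = n)
}

#' Assess homogeneity of variances across groups
#'
#' The Brown-Forsythe variant of Levene's test: a one-way F test on absolute
#' deviations from the group medians. Robust to non-normality, which is why
#' it gates the parametric branches of the adaptive engine.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return A list with `method` (`"levene_median"` or `"not_assessable"`),
#'   `statistic` (F), `p`, and degrees of freedom `df1`, `df2`. Groups with
#'   fewer than 2 observations make the check not assessable (the engine
#'   then takes the heterogeneous/non-parametric path).
#' @export
assess_variance_homogeneity <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_validation("`groups` must be a list of >= 2 numeric vectors.")
  }
  ns <- lengths(groups)
  if (any(ns < 2)) {
    return(list(method = "not_assessable", statistic = NA_real_,
                p = NA_real_, df1 = NA_real_, df2 = NA_real_))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  lv <- car::leveneTest(y ~ g, center = stats::median)
  list(method = "levene_median",
       statistic = lv[["F value"]][1], p = lv[["Pr(>F)"]][1],
       df1 = lv[["Df"]][1], df2 = lv[["Df"]][2])
}

#' Build the full assumption report for a set of groups
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return A list of class `assumption_report` with `normality` (one
#'   [assess_normality()] result per group), `variance`
#'   ([assess_variance_homogeneity()] result), and `min_n`.
#' @export
assess_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_validation("`groups` must be a list of >= 2 numeric vectors.")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  structure(list(
    normality = purrr::map(groups, assess_normality),
    variance = assess_variance_homogeneity(groups),
    min_n = min(lengths(groups))
  ), class = "assumption_report")
}

#' Select the statistical test for a comparison
#'
#' The decision table of the adaptive engine:
#' * all groups normal (every normality p > `alpha_assumption`), variances
#'   homogeneous (Levene p > `alpha_assumption`) and every group n >= 3 →
#'   Student's t (2 groups) / one-way ANOVA (k > 2);
#' * all groups normal but variances unequal → Welch's t / Welch's ANOVA;
#' * otherwise (non-normality, a not-assessable check, or any group with
#'   fewer than three observations) → Wilcoxon rank-sum / Kruskal-Wallis.
#'
#' @param report An `assumption_report` from [assess_groups()].
#' @param k Number of groups compared (must match the report).
#' @param alpha_assumption Significance level of the assumption checks
#'   (default 0.05).
#' @return One of `"student_t"`, `"welch_t"`, `"wilcoxon"`, `"anova"`,
#'   `"welch_anova"`, `"kruskal_wallis"`.
#' @export
select_test <- function(report, k = length(report$normality),
                        alpha_assumption = 0.05) {
  if (!inherits(report, "assumption_report")) {
    stop_validation("`report` must come from assess_groups().")
  }
  if (k < 2) stop_validation("`k` must be >= 2.")
  if (k != length(report$normality)) {
    stop_validation("`k` does not match the number of groups in `report`.")
  }
  norm_p <- purrr::map_dbl(report$normality, "p")
  norm_ok <- !anyNA(norm_p) && all(norm_p > alpha_assumption)
  all_n_ok <- report$min_n >= 3
  var_p <- report$variance$p
  var_ok <- !is.na(var_p) && var_p > alpha_assumption

  if (norm_ok && all_n_ok && var_ok) {
    if (k == 2) "student_t" else "anova"
  } else if (norm_ok && all_n_ok && !is.na(var_p)) {
    if (k == 2) "welch_t" else "welch_anova"
  } else {
    if (k == 2) "wilcoxon" else "kruskal_wallis"
  }
}
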