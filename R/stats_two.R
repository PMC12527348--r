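#' Run a two-group test on tail lengths
#'
#' @param a,b Numeric vectors of tail lengths for the two groups.
#' @param test_id `"student_t"` (pooled variance, df = n1 + n2 - 2),
#'   `"welch_t"` (Welch-Satterthwaite df) or `"wilcoxon"`. The Wilcoxon test
#'   uses the exact null distribution when both groups have n <= 25 and there
#'   are no ties, otherwise the normal approximation with tie and continuity
#'   correction.
#' @param labels Optional character vector of length 2 naming the groups.
#' @return A `polya_test` object: list with `test_id`, `statistic`,
#'   `p_value`, `df` (NA for wilcoxon), `group_labels`, `group_ns`,
#'   `posthoc = NULL`.
#' @export
run_two_group_test <- function(a, b, test_id = c("wilcoxon", "student_t", "welch_t"),
                               labels = c("a", "b")) {
  test_id <- match.arg(test_id)
  if (!is.numeric(a) || !is.numeric(b)) {
    stop_validation("`a` and `b` must be numeric vectors.")
  }
  if (length(a) < 1 || length(b) < 1) {
    stop_validation("Both groups must have at least one observation.")
  }
  if (test_id %in% c("student_t", "welch_t")) {
    if (length(a) < 2 || length(b) < 2) {
      stop_validation("t-tests require at least 2 observations per group.")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      abort("Both groups have zero variance; the t statistic is undefined.",
            class = "polytail_degenerate_error")
    }
    ht <- stats::t.test(b, a, var.equal = (test_id == "student_t"))
    statistic <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 &&
      anyDuplicated(c(a, b)) == 0
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    statistic <- unname(ht$statistic)
    df <- NA_real_
    p <- ht$p.value
    if (is.nan(p)) p <- 1  # all pooled values tied: no rank evidence
  }
  structure(list(
    test_id = test_id, statistic = statistic, p_value = p, df = df,
    group_labels = labels, group_ns = c(length(a), length(b)),
    posthoc = NULL
  ), class = "polya_test")
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(treated) - mean(control)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. Positive
#' values mean longer tails in the treated group.
#'
#' @param control,treated Numeric vectors (n >= 2 each).
#' @return The effect size, or `NA` (with a warning) when the pooled
#'   variance is zero.
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6)) # 3
#' @export
cohens_d <- function(control, treated) {
  if (length(control) < 2 || length(treated) < 2) {
    stop_validation("Cohen's d requires at least 2 observations per group.")
  }
  n1 <- length(control); n2 <- length(treated)
  sp2 <- ((n1 - 1) * stats::var(control) + (n2 - 1) * stats::var(treated)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    warn("Pooled variance is zero; Cohen's d is undefined.")
    return(NA_real_)
  }
  (mean(treated) - mean(control)) / sqrt(sp2)
}

#' Log2 fold change of mean tail length
#'
#' `log2(mean_treated / mean_control)`. Negative values indicate tail
#' shortening in the treated group ("collapsed"), positive values tail
#' lengthening ("expansion").
#'
#' @param mean_control,mean_treated Positive mean tail lengths (nt).
#'   Vectorized.
#' @return `log2(mean_treated / mean_control)`.
#' @export
log2_fold_change <- function(mean_control, mean_treated) {
  if (any(!is.finite(mean_control)) || any(!is.finite(mean_treated)) ||
      any(mean_control <= 0) || any(mean_treated <= 0)) {
    stop_validation("Means must be finite and > 0 to take a log2 ratio.")
  }
  log2(mean_treated / mean_control)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper around [stats::p.adjust()] that (unlike the base default)
#' excludes missing p-values from the number of tests `m`, preserves their
#' positions, and validates the input range. `"fdr"` is an alias of `"BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s allowed.
#' @param method One of `"holm"`, `"hochberg"`, `"hommel"`, `"bonferroni"`,
#'   `"BH"`, `"BY"`, `"fdr"`, `"none"` (case-insensitive).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "BH") # all 0.03
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (!is.numeric(p)) stop_validation("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_validation("p-values must lie in [0, 1].")
  }
  allowed <- c("holm", "hochberg", "hommel", "bonferroni", "BH", "BY",
               "fdr", "none")
  hit <- match(tolower(method), tolower(allowed))
  if (is.na(hit)) {
    stop_validation(sprintf(
      "Unknown adjustment method '%s' (use one of %s).",
      method, paste(allowed, collapse = ", ")
    ))
  }
  method <- allowed[hit]
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = method, n = sum(ok))
  out
}
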