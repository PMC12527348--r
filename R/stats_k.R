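#' Run an omnibus k-group test with pairwise post-hoc comparisons
#'
#' @param groups Named list of numeric vectors (k >= 3), one per group.
#' @param test_id `"anova"` (one-way ANOVA, Tukey HSD post-hoc),
#'   `"welch_anova"` ([stats::oneway.test()] with Welch correction,
#'   Games-Howell post-hoc) or `"kruskal_wallis"` (tie-corrected H statistic,
#'   Dunn post-hoc with Bonferroni correction).
#' @return A `polya_test` object whose `posthoc` element is a tibble with
#'   columns `pair`, `statistic`, `p_adjusted`, `method` covering all
#'   k(k-1)/2 pairs.
#' @export
run_k_group_test <- function(groups,
                             test_id = c("kruskal_wallis", "anova", "welch_anova")) {
  test_id <- match.arg(test_id)
  if (!is.list(groups) || length(groups) < 3) {
    stop_validation("`groups` must be a list of >= 3 numeric vectors (use run_two_group_test() for k = 2).")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  labels <- names(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, lengths(groups)), levels = labels)

  if (test_id == "anova") {
    fit <- stats::aov(y ~ g)
    tab <- summary(fit)[[1]]
    statistic <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    df <- tab[["Df"]][1]
    tk <- stats::TukeyHSD(fit)$g
    posthoc <- tibble(
      pair = rownames(tk),
      statistic = unname(tk[, "diff"]),
      p_adjusted = unname(tk[, "p adj"]),
      method = "tukey_hsd"
    )
  } else if (test_id == "welch_anova") {
    ht <- stats::oneway.test(y ~ g, var.equal = FALSE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter[1])
    posthoc <- games_howell(groups)
  } else {
    ht <- suppressWarnings(stats::kruskal.test(y, g))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
    if (is.nan(statistic)) {  # every observation tied: no rank evidence
      statistic <- 0
      p <- 1
    }
    posthoc <- dunn_posthoc(groups)
  }
  structure(list(
    test_id = test_id, statistic = statistic, p_value = p, df = df,
    group_labels = labels, group_ns = unname(lengths(groups)),
    posthoc = posthoc
  ), class = "polya_test")
}

# Games-Howell pairwise comparisons: Welch t per pair, p from the
# studentized range with k groups and Welch-Satterthwaite df.
games_howell <- function(groups) {
  labels <- names(groups)
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    se2 <- unname(v[i] / n[i] + v[j] / n[j])
    tstat <- unname(m[j] - m[i]) / sqrt(se2)
    df <- se2^2 / unname((v[i] / n[i])^2 / (n[i] - 1) +
                           (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble(pair = paste0(labels[j], "-", labels[i]),
           statistic = tstat, p_adjusted = p, method = "games_howell")
  })
  dplyr::bind_rows(res)
}

# Dunn's pairwise z-tests on pooled ranks with tie correction;
# two-sided p, Bonferroni-adjusted over the k(k-1)/2 comparisons.
dunn_posthoc <- function(groups) {
  labels <- names(groups)
  k <- length(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  ncomp <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    se <- sqrt(sigma2_base * unname(1 / n[i] + 1 / n[j]))
    z <- (rbar[[j]] - rbar[[i]]) / se
    if (!is.finite(z)) z <- 0  # all observations tied
    p <- 2 * stats::pnorm(-abs(z))
    tibble(pair = paste0(labels[j], "-", labels[i]),
           statistic = z, p_adjusted = min(1, p * ncomp),
           method = "dunn_bonferroni")
  })
  dplyr::bind_rows(res)
}

#' @export
print.polya_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (groups: %s; n = %s)\n",
              x$test_id, x$statistic, x$p_value,
              paste(x$group_labels, collapse = ", "),
              paste(x$group_ns, collapse = ", ")))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc comparisons:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @export
tidy.polya_test <- function(x, ...) {
  if (is.null(x$posthoc)) {
    tibble(test_id = x$test_id, statistic = x$statistic,
           p_value = x$p_value, df = x$df)
  } else {
    mutate(x$posthoc, test_id = x$test_id, .before = 1)
  }
}

#' @export
glance.polya_test <- function(x, ...) {
  tibble(test_id = x$test_id, statistic = x$statistic, p_value = x$p_value,
         df = x$df, k = length(x$group_labels), n_total = sum(x$group_ns))
}
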