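test_that("normality assessment routes by sample size and degeneracy", {
  expect_equal(assess_normality(c(50, 50, 50))$method, "not_assessable")
  expect_equal(assess_normality(c(10, 20))$method, "not_assessable")
  set.seed(11)
  small <- rnorm(100, 70, 10)
  res <- assess_normality(small)
  expect_equal(res$method, "shapiro")
  expect_equal(res$p, shapiro.test(small)$p.value)
  big <- rnorm(6000, 70, 10)
  res_big <- assess_normality(big)
  expect_equal(res_big$method, "lilliefors")
  expect_equal(res_big$p, nortest::lillie.test(big)$p.value)
  expect_error(assess_normality(c(1, NA, 3)), class = "polytail_validation_error")
})

test_that("variance homogeneity matches the median-centred Levene formula", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50))
  res <- assess_variance_homogeneity(g)
  oracle <- oracle_levene_median(g)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  same <- assess_variance_homogeneity(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # any group with n < 2 is not assessable
  expect_equal(
    assess_variance_homogeneity(list(a = 1, b = c(1, 2), c = c(3, 4)))$method,
    "not_assessable"
  )
})

test_that("the decision tree routes the four canonical branches for k = 2 and k > 2", {
  set.seed(21)
  normal_homo <- list(a = rnorm(40, 70, 10), b = rnorm(40, 75, 10))
  normal_hetero <- list(a = rnorm(40, 70, 3), b = rnorm(40, 75, 30))
  skewed <- list(a = rexp(40, 0.05), b = rexp(40, 0.03))
  tiny <- list(a = c(50, 60), b = rnorm(40, 70, 10))

  expect_equal(select_test(assess_groups(normal_homo), 2), "student_t")
  expect_equal(select_test(assess_groups(normal_hetero), 2), "welch_t")
  expect_equal(select_test(assess_groups(skewed), 2), "wilcoxon")
  expect_equal(select_test(assess_groups(tiny), 2), "wilcoxon")

  normal_homo3 <- c(normal_homo, list(c = rnorm(40, 72, 10)))
  normal_hetero3 <- c(normal_hetero, list(c = rnorm(40, 72, 60)))
  skewed3 <- c(skewed, list(c = rexp(40, 0.02)))
  tiny3 <- list(a = c(50, 60), b = rnorm(40, 70, 10), c = rnorm(40, 70, 10))
  expect_equal(select_test(assess_groups(normal_homo3), 3), "anova")
  expect_equal(select_test(assess_groups(normal_hetero3), 3), "welch_anova")
  expect_equal(select_test(assess_groups(skewed3), 3), "kruskal_wallis")
  expect_equal(select_test(assess_groups(tiny3), 3), "kruskal_wallis")

  expect_error(select_test(assess_groups(normal_homo), 1),
               class = "polytail_validation_error")
})

test_that("two-group tests agree with enumeration and closed-form oracles", {
  # exact Wilcoxon: hand-derivable extreme split, p = 2/20
  res <- run_two_group_test(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))

  # symmetric Student case
  sym <- run_two_group_test(c(1, 2, 3, 4), c(1, 2, 3, 4), "student_t")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  a <- c(10, 12, 14, 16); b <- c(11, 13, 15, 17)
  welch <- run_two_group_test(a, b, "welch_t")
  expect_equal(welch$p_value, oracle_welch_t(a, b)$p, tolerance = 1e-10)
  student <- run_two_group_test(a, b, "student_t")
  expect_equal(student$p_value, oracle_student_t(a, b)$p, tolerance = 1e-10)

  expect_error(run_two_group_test(c(5, 5, 5), c(5, 5, 5), "student_t"),
               class = "polytail_degenerate_error")
  expect_error(run_two_group_test(numeric(0), 1:3, "wilcoxon"),
               class = "polytail_validation_error")
})

test_that("exact Wilcoxon equals full enumeration on random tie-free inputs", {
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    vals <- sample(1:500, n1 + n2)   # tie-free by construction
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    expect_equal(run_two_group_test(a, b, "wilcoxon")$p_value,
                 oracle_wilcoxon_exact(a, b), tolerance = 1e-12)
  }
})

test_that("k-group omnibus statistics match literal-formula oracles", {
  same <- list(a = 1:5, b = 1:5, c = 1:5)
  kw0 <- run_k_group_test(same, "kruskal_wallis")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_true(all(kw0$posthoc$p_adjusted == 1))

  sep <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- run_k_group_test(sep, "kruskal_wallis")
  # tie-free closed form 12/(N(N+1)) * sum(n_i * Rbar_i^2) - 3(N+1)
  rbars <- c(2, 5, 8)
  h_hand <- 12 / (9 * 10) * sum(3 * rbars^2) - 3 * 10
  expect_equal(kw$statistic, h_hand, tolerance = 1e-10)
  expect_equal(kw$statistic, oracle_kruskal(sep)$statistic, tolerance = 1e-10)

  set.seed(41)
  norm3 <- list(a = rnorm(20, 70, 10), b = rnorm(20, 74, 10),
                c = rnorm(20, 78, 10))
  av <- run_k_group_test(norm3, "anova")
  expect_equal(av$p_value, oracle_anova_f(norm3)$p, tolerance = 1e-10)
  expect_equal(nrow(av$posthoc), 3)
  expect_true(all(av$posthoc$method == "tukey_hsd"))

  wa <- run_k_group_test(norm3, "welch_anova")
  expect_equal(wa$p_value, oracle_welch_anova(norm3)$p, tolerance = 1e-10)
  expect_true(all(wa$posthoc$method == "games_howell"))

  expect_error(run_k_group_test(list(a = 1:3, b = 4:6), "anova"),
               class = "polytail_validation_error")
})

test_that("Games-Howell matches an independent reference on a frozen fixture", {
  groups <- list(a = c(10, 12, 11, 14, 13),
                 b = c(20, 25, 23, 28, 30, 27),
                 c = c(15, 16, 14, 18))
  gh <- run_k_group_test(groups, "welch_anova")$posthoc
  expect_equal(gh$pair, c("b-a", "c-a", "c-b"))
  expect_equal(gh$statistic, c(8.24131389151, 3.38240712601, -5.71309766926),
               tolerance = 1e-8)
  # the reference evaluates the studentized range by interpolation, so its
  # p-values agree only to ~1e-4 with the exact distribution function
  expect_equal(gh$p_adjusted,
               c(0.000178821512373, 0.031972613208, 0.00143029945497),
               tolerance = 1e-4)
})

test_that("Dunn post-hoc reproduces the rank z formula with Bonferroni capping", {
  groups <- list(a = c(1, 2, 2, 3), b = c(4, 5, 6), c = c(7, 8, 8, 9, 10))
  dn <- run_k_group_test(groups, "kruskal_wallis")$posthoc
  expect_true(all(dn$method == "dunn_bonferroni"))
  # literal recomputation
  y <- unlist(groups); N <- length(y); r <- rank(y)
  rbar <- tapply(r, rep(1:3, lengths(groups)), mean)
  ties <- table(y)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ba <- (rbar[2] - rbar[1]) / sqrt(s2 * (1 / 4 + 1 / 3))
  p_ba <- min(1, 2 * pnorm(-abs(z_ba)) * 3)
  expect_equal(dn$statistic[dn$pair == "b-a"], unname(z_ba), tolerance = 1e-10)
  expect_equal(dn$p_adjusted[dn$pair == "b-a"], unname(p_ba), tolerance = 1e-10)
  expect_true(all(dn$p_adjusted <= 1))
})

test_that("effect sizes follow their definitions and invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), 3)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(51)
  a <- rnorm(20, 70, 10); b <- rnorm(20, 80, 12)
  expect_equal(cohens_d(a * 3, b * 3), cohens_d(a, b))   # scale invariance
  expect_warning(d0 <- cohens_d(c(5, 5), c(5, 5)), "zero")
  expect_true(is.na(d0))

  expect_equal(log2_fold_change(50, 100), 1)
  expect_equal(log2_fold_change(80, 80), 0)
  expect_equal(log2_fold_change(100, 50), -1)   # the "collapsed" direction
  expect_error(log2_fold_change(0, 50), class = "polytail_validation_error")
})

test_that("p-value adjustment matches stepwise re-implementations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  expect_equal(adjust_pvalues(0.2, "holm"), 0.2)   # m = 1 identity
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
  # "fdr" is an alias of BH; case-insensitive method names
  set.seed(61)
  p <- runif(50)
  expect_equal(adjust_pvalues(p, "fdr"), adjust_pvalues(p, "BH"))
  expect_equal(adjust_pvalues(p, "Hochberg"), adjust_pvalues(p, "hochberg"))

  # missing values keep their place and are excluded from m
  pna <- c(0.01, NA, 0.03)
  adj <- adjust_pvalues(pna, "bonferroni")
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], c(0.02, 0.06))   # m = 2, not 3

  for (i in 1:100) {
    p <- runif(sample(2:40, 1))
    for (m in c("holm", "hochberg", "bonferroni", "BH", "BY")) {
      got <- adjust_pvalues(p, m)
      expect_equal(got, oracle_adjust(p, m), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-15) && all(got <= 1))
    }
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"),
               class = "polytail_validation_error")
  expect_error(adjust_pvalues(0.5, "tukey"),
               class = "polytail_validation_error")
})
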