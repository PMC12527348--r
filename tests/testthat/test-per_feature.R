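test_that("two-group per-feature stats detect a planted shift with the right sign", {
  sim <- quick_sim(n_features = 12, n_affected = 3, shift = -30, sd = 10,
                   reads = 50, seed = 101)
  st <- per_feature_two_group(sim$polya, "transcript_id",
                              control_group = "CTR", treated_group = "HIGH")
  hit <- st[st$feature_id %in% sim$truth$feature_id[sim$truth$affected], ]
  expect_true(all(hit$p_value < 0.05))
  expect_true(all(hit$log2fc < 0))          # shift -30 nt: treated shorter
  expect_true(all(hit$dpg_call == "collapsed"))
  expect_equal(nrow(st), 12)
  expect_true(all(st$padj >= st$p_value - 1e-15, na.rm = TRUE))
})

test_that("identical groups yield p = 1, zero effects and an ns call", {
  polya <- dplyr::bind_rows(
    make_polya(paste0("a", 1:6), "t1", c(40, 50, 60, 40, 50, 60), group = "CTR"),
    make_polya(paste0("b", 1:6), "t1", c(40, 50, 60, 40, 50, 60),
               group = "HIGH", sample_name = "s2")
  )
  st <- per_feature_two_group(polya, "transcript_id", "CTR", "HIGH",
                              mode = "wilcoxon_only")
  expect_equal(st$p_value, 1)
  expect_equal(st$cohens_d, 0)
  expect_equal(st$log2fc, 0)
  expect_equal(st$dpg_call, "ns")
})

test_that("adaptive mode falls back to Wilcoxon for tiny or degenerate features", {
  polya <- dplyr::bind_rows(
    make_polya(paste0("a", 1:2), "t1", c(50, 52), group = "CTR"),
    make_polya(paste0("b", 1:30), "t1", round(rnorm(30, 70, 10)),
               group = "HIGH", sample_name = "s2"),
    # all-constant feature: t statistic undefined, must route to wilcoxon
    make_polya(paste0("c", 1:5), "t2", 60, group = "CTR"),
    make_polya(paste0("d", 1:5), "t2", 60, group = "HIGH", sample_name = "s2")
  )
  st <- per_feature_two_group(polya, "transcript_id", "CTR", "HIGH",
                              mode = "adaptive")
  expect_equal(st$test_id[st$feature_id == "t1"], "wilcoxon")  # n = 2 branch
  expect_equal(st$test_id[st$feature_id == "t2"], "wilcoxon")  # degenerate
  expect_equal(st$dpg_call[st$feature_id == "t2"], "ns")
})

test_that("features under min_n are reported but not tested", {
  polya <- dplyr::bind_rows(
    make_polya(paste0("a", 1:10), "t1", round(rnorm(10, 70, 5)), group = "CTR"),
    make_polya(paste0("b", 1:2), "t1", c(60, 61), group = "HIGH",
               sample_name = "s2")
  )
  st <- per_feature_two_group(polya, "transcript_id", "CTR", "HIGH", min_n = 5)
  expect_equal(nrow(st), 1)
  expect_true(is.na(st$p_value))
  expect_equal(st$dpg_call, "not_tested")
  expect_equal(st$n_treated, 2)

  expect_error(
    per_feature_two_group(polya, "transcript_id", "CTR", "MISSING"),
    class = "polytail_validation_error", regexp = "MISSING"
  )
})

test_that("k-group per-feature stats plant and attribute effects across 3 groups", {
  sim <- quick_sim(n_features = 10, n_affected = 2, shift = c(HIGH = 40),
                   sd = 10, reads = 50, groups = c("CTR", "LOW", "HIGH"),
                   seed = 103)
  st <- per_feature_k_group(sim$polya, "transcript_id", mode = "adaptive")
  affected <- sim$truth$feature_id[sim$truth$affected]
  expect_true(all(st$padj[st$feature_id %in% affected] < 0.05))
  expect_true(all(st$dpg_call[st$feature_id %in% affected] == "dpg"))
  expect_false("log2fc" %in% names(st))
  ph <- posthoc_table(st)
  expect_setequal(unique(ph$pair[ph$feature_id == affected[1]]),
                  c("HIGH-CTR", "LOW-CTR", "LOW-HIGH"))

  # identical distributions: ns everywhere
  flat <- make_polya(paste0("r", 1:30), "t1", rep(rep_len(c(40, 50, 60), 10), 3),
                     sample_name = rep(c("s1", "s2", "s3"), each = 10),
                     group = rep(c("A", "B", "C"), each = 10))
  st0 <- per_feature_k_group(flat, "transcript_id", mode = "kruskal_only")
  expect_equal(st0$p_value, 1)
  expect_equal(st0$dpg_call, "ns")

  expect_error(
    per_feature_k_group(make_polya("r1", "t1", 50), "transcript_id"),
    class = "polytail_validation_error", regexp = "two_group"
  )
})

test_that("kruskal_only and adaptive differ exactly by test selection on clean data", {
  sim <- quick_sim(n_features = 6, n_affected = 0, sd = 10, reads = 40,
                   groups = c("CTR", "LOW", "HIGH"), seed = 105)
  forced <- per_feature_k_group(sim$polya, "transcript_id", mode = "kruskal_only")
  adaptive <- per_feature_k_group(sim$polya, "transcript_id", mode = "adaptive")
  expect_true(all(forced$test_id == "kruskal_wallis"))
  # normal equal-variance simulated data: adaptive picks ANOVA for most features
  expect_true(mean(adaptive$test_id == "anova") > 0.5)
  expect_identical(forced$feature_id, adaptive$feature_id)
})

test_that("DPG calls honour the strict alpha threshold and direction", {
  stats <- tibble::tibble(
    feature_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(-0.3, 0.4, 0.5, -0.2),
    padj = c(0.049, 0.05, NA, 0.002)
  )
  called <- call_dpgs(stats, alpha = 0.05)
  expect_equal(called$dpg_call, c("collapsed", "ns", "not_tested", "collapsed"))
  # recalling at a looser alpha flips the boundary case
  expect_equal(call_dpgs(stats, alpha = 0.051)$dpg_call[2], "expansion")
})

test_that("the global group test pools reads and selects a coherent test", {
  sim3 <- quick_sim(n_features = 20, n_affected = 20,
                    shift = c(LOW = -10, HIGH = -20), sd = 25, reads = 100,
                    groups = c("CTR", "LOW", "HIGH"), seed = 107)
  gt <- global_group_test(sim3$polya)
  expect_s3_class(gt, "polya_test")
  expect_equal(length(gt$group_labels), 3)
  expect_true(gt$p_value < 0.001)
  expect_equal(nrow(gt$posthoc), 3)
  expect_true(all(gt$posthoc$p_adjusted < 0.05))

  # degenerate two-group case: constant identical groups fall through to
  # wilcoxon and report no difference
  const <- dplyr::bind_rows(
    make_polya(paste0("a", 1:5), "t1", 50, group = "A"),
    make_polya(paste0("b", 1:5), "t1", 50, group = "B", sample_name = "s2")
  )
  g2 <- global_group_test(const)
  expect_equal(g2$test_id, "wilcoxon")
  expect_equal(g2$p_value, 1)

  expect_error(global_group_test(make_polya("r1", "t1", 50)),
               class = "polytail_validation_error")
})
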