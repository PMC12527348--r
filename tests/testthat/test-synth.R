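test_that("simulation is reproducible and honours the design", {
  d <- simulation_design(n_features = 10, seed = 7)
  s1 <- simulate_polya_table(d)
  s2 <- simulate_polya_table(d)
  expect_identical(s1, s2)                           # byte-identical given seed
  expect_equal(sum(s1$truth$affected), 0)
  expect_equal(nrow(s1$polya), 10 * 2 * 3 * 30)
  expect_true(all(s1$polya$polyA_length >= 1))

  # planted +20 nt shift recovered within CLT bounds
  ds <- simulation_design(n_features = 5, n_affected = 5, shift = 20,
                          baseline_sd = 10, reads_per_feature = 200,
                          n_samples_per_group = 1, seed = 8)
  ss <- simulate_polya_table(ds)
  diffs <- ss$polya |>
    dplyr::group_by(transcript_id, group) |>
    dplyr::summarise(m = mean(polyA_length), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m) |>
    dplyr::mutate(delta = HIGH - CTR)
  se <- 10 * sqrt(2 / 200)
  expect_true(all(abs(diffs$delta - 20) < 3 * se + 0.5))  # +0.5 for rounding
  expect_true(all(ss$truth$direction == "expansion"))

  expect_error(simulation_design(n_features = 5, seed = 1, n_affected = 9),
               class = "polytail_validation_error")
  expect_error(simulation_design(n_features = 5),
               class = "polytail_validation_error")   # seed is mandatory
  expect_error(simulation_design(n_features = 5, seed = 1, shift = -200,
                                 n_affected = 2),
               class = "polytail_validation_error")   # means below 1 nt
})

test_that("duplicate and multimap fractions plant the taxonomy the qc module sees", {
  d <- simulation_design(n_features = 10, reads_per_feature = 100,
                         n_samples_per_group = 1, groups = c("CTR", "HIGH"),
                         duplicate_fraction = 0.1, multimap_fraction = 0.05,
                         seed = 9)
  s <- simulate_polya_table(d)
  base_reads <- 10 * 100 * 2
  cls <- classify_read_assignments(s$polya)
  counts <- setNames(cls$counts$n_reads, cls$counts$class)
  expect_equal(sum(counts), base_reads)
  # binomial oracle: ~10% duplicated, ~5% multiple, 3 sigma tolerance
  expect_lt(abs(counts[["duplicated"]] - 0.10 * base_reads),
            3 * sqrt(base_reads * 0.1 * 0.9) + 1)
  expect_lt(abs(counts[["multiple"]] - 0.05 * base_reads),
            3 * sqrt(base_reads * 0.05 * 0.95) + 1)
  # extra records reuse the molecule's tail length on another transcript
  dup_ids <- cls$reads$read_id[cls$reads$class != "unique"][1:5]
  for (rid in dup_ids) {
    recs <- s$polya[s$polya$read_id == rid, ]
    expect_equal(length(unique(recs$polyA_length)), 1)
    expect_gt(length(unique(recs$transcript_id)), 1)
  }
})

test_that("BAM round trip preserves planted triples and flags secondaries", {
  dir <- withr::local_tempdir()
  tab <- make_polya(
    read_id = c("r1", "r1", "r2", "r3"),
    transcript_id = c("t1", "t2", "t1", "t3"),
    polyA_length = c(44, 44, 80, 61)
  )
  bam <- write_synthetic_bam(tab, references = c("t1", "t2", "t3"),
                             path = file.path(dir, "rt.bam"))
  # independent read-back of FLAG bits via Rsamtools, not extract_polya
  flags <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag"))
  )[[1]]
  expect_equal(sum(bitwAnd(flags$flag, 256L) > 0), 1)
  expect_equal(flags$qname[bitwAnd(flags$flag, 256L) > 0], "r1")

  polya <- extract_polya(tibble::tibble(bam_path = bam, sample_name = "s1",
                                        group = "CTR"))
  # primary-only extraction recovers the first record of each read id
  first <- tab[!duplicated(tab$read_id), ]
  expect_equal(polya$read_id, first$read_id)
  expect_equal(polya$transcript_id, first$transcript_id)
  expect_equal(polya$polyA_length, first$polyA_length)

  # empty table still produces a valid header-only BAM
  empty <- write_synthetic_bam(tab[0, ], references = "t1",
                               path = file.path(dir, "empty.bam"))
  out <- extract_polya(tibble::tibble(bam_path = empty, sample_name = "s",
                                      group = "g"))
  expect_equal(nrow(out), 0)
  expect_equal(skip_report(out)$scanned, 0)

  expect_error(
    write_synthetic_bam(tab, references = "t1", path = file.path(dir, "x.bam")),
    class = "polytail_validation_error", regexp = "t2"
  )
})

test_that("a full synthetic experiment flows through extraction to recovery", {
  dir <- withr::local_tempdir()
  design <- simulation_design(n_features = 15, n_affected = 4, shift = 25,
                              baseline_sd = 10, reads_per_feature = 30,
                              n_samples_per_group = 2, seed = 11)
  exp <- suppressMessages(write_synthetic_experiment(design, dir))
  samples <- suppressMessages(read_samples_table(exp$samples_csv))
  polya <- extract_polya(samples)
  # extraction reproduces the simulated table exactly (primary-only, no dups)
  expect_equal(nrow(polya), nrow(exp$polya))
  expect_equal(sort(polya$read_id), sort(exp$polya$read_id))
  reord <- exp$polya[match(polya$read_id, exp$polya$read_id), ]
  expect_equal(polya$polyA_length, reord$polyA_length)
  expect_equal(polya$transcript_id, reord$transcript_id)

  ann <- attach_gene_ids(polya, parse_gtf_transcript_gene_map(exp$gtf))
  expect_false(anyNA(ann$gene_id))
  flt <- filter_min_tails(ann, "gene_id", 10)
  st <- per_feature_two_group(flt, "gene_id", "CTR", "HIGH")
  affected_genes <- exp$truth$gene_id[exp$truth$affected]
  hits <- st$feature_id[st$dpg_call == "expansion"]
  expect_true(all(affected_genes %in% hits))
})
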