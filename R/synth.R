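#' Describe a synthetic polyadenylation experiment
#'
#' Defines the ground truth for a simulated study: how many features
#' (transcripts), the group layout, the baseline tail-length distribution,
#' which features carry a planted group shift, and how many reads support
#' each feature. Defaults emulate a typical nanopore run: baseline mean tail
#' lengths drawn uniformly in 50-100 nt (the commonly observed range for
#' median poly(A) tails) around a 70 nt centre with sd 25 nt.
#'
#' @param n_features Number of transcripts.
#' @param groups Character vector of group labels (first label is the
#'   reference; shifts apply to the others).
#' @param n_samples_per_group Samples per group.
#' @param reads_per_feature Reads per feature per sample.
#' @param family Baseline distribution: `"normal"` (truncated at 1),
#'   `"lognormal"`, or `"nbinom"` (shifted by 1 so lengths are >= 1).
#' @param baseline_mean,baseline_sd Centre and spread (nt) of the tail
#'   distribution. With `vary_baseline = TRUE` per-feature baselines are
#'   drawn uniformly in `baseline_mean` +/- 20 nt.
#' @param vary_baseline Draw a different baseline mean per feature.
#' @param n_affected Number of features receiving the planted shift.
#' @param shift Mean shift (nt) applied to affected features. Either a
#'   single number (applied to every non-reference group) or a named vector
#'   of per-group shifts. Must leave all means >= 1.
#' @param duplicate_fraction Fraction of reads duplicated once (read id
#'   reappears on a second transcript with the same tail length).
#' @param multimap_fraction Fraction of reads additionally multi-mapped
#'   (read id appears three times in total).
#' @param transcripts_per_gene Transcripts per gene in the implied
#'   annotation (default 1).
#' @param seed Mandatory integer seed; the design is only reproducible with
#'   it.
#' @return A `simulation_design` list, validated.
#' @export
simulation_design <- function(n_features = 200,
                              groups = c("CTR", "HIGH"),
                              n_samples_per_group = 3,
                              reads_per_feature = 30,
                              family = c("normal", "lognormal", "nbinom"),
                              baseline_mean = 70, baseline_sd = 25,
                              vary_baseline = TRUE,
                              n_affected = 0, shift = 20,
                              duplicate_fraction = 0,
                              multimap_fraction = 0,
                              transcripts_per_gene = 1,
                              seed) {
  family <- match.arg(family)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_validation("`seed` is mandatory and must be a single integer.")
  }
  if (length(groups) < 2 || anyDuplicated(groups) > 0) {
    stop_validation("`groups` must be >= 2 distinct labels.")
  }
  if (n_affected > n_features) {
    stop_validation("`n_affected` cannot exceed `n_features`.")
  }
  if (baseline_sd <= 0 || baseline_mean < 1) {
    stop_validation("`baseline_mean` must be >= 1 and `baseline_sd` > 0.")
  }
  if (any(duplicate_fraction < 0 | duplicate_fraction > 1) ||
      any(multimap_fraction < 0 | multimap_fraction > 1)) {
    stop_validation("Fractions must lie in [0, 1].")
  }
  shifted_groups <- groups[-1]
  if (is.null(names(shift))) {
    if (length(shift) != 1) {
      stop_validation("Unnamed `shift` must be a single number.")
    }
    shift <- setNames(rep(shift, length(shifted_groups)), shifted_groups)
  } else {
    unknown <- setdiff(names(shift), groups)
    if (length(unknown) > 0) {
      stop_validation(sprintf("`shift` names not in `groups`: %s.",
                              paste(unknown, collapse = ", ")))
    }
  }
  lo_mean <- if (vary_baseline) baseline_mean - 20 else baseline_mean
  if (lo_mean + min(c(shift, 0)) < 1) {
    stop_validation("Planted shifts would push mean tail lengths below 1 nt.")
  }
  structure(list(
    n_features = as.integer(n_features), groups = groups,
    n_samples_per_group = as.integer(n_samples_per_group),
    reads_per_feature = as.integer(reads_per_feature),
    family = family, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, vary_baseline = vary_baseline,
    n_affected = as.integer(n_affected), shift = shift,
    duplicate_fraction = duplicate_fraction,
    multimap_fraction = multimap_fraction,
    transcripts_per_gene = as.integer(transcripts_per_gene),
    seed = as.integer(seed)
  ), class = "simulation_design")
}

draw_lengths <- function(n, mean, sd, family) {
  raw <- switch(
    family,
    normal = stats::rnorm(n, mean, sd),
    lognormal = {
      sigma2 <- log(1 + sd^2 / mean^2)
      stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2,
                    sdlog = sqrt(sigma2))
    },
    nbinom = {
      mu <- mean - 1
      size <- if (sd^2 > mu) mu^2 / (sd^2 - mu) else 1e6
      stats::rnbinom(n, mu = mu, size = size) + 1
    }
  )
  pmax(1L, as.integer(round(raw)))
}

#' Simulate a per-read poly(A) table with known ground truth
#'
#' Draws integer tail lengths (>= 1) per feature, sample and group from the
#' design's distribution, planting the configured mean shifts in the
#' affected features (the first `n_affected` feature ids). Optionally reuses
#' read ids to emulate duplicated (x2) and multi-mapped (x3) read-to-
#' transcript assignments; the extra records carry the same tail length —
#' the same molecule seen on another transcript — on a different transcript
#' of the same simulated gene where one exists.
#'
#' @param design A [simulation_design()].
#' @return A list with `polya` (tibble: `read_id`, `transcript_id`,
#'   `polyA_length`, `sample_name`, `group`, `gene_id`), `truth` (tibble:
#'   `feature_id`, `gene_id`, `affected`, `direction`, one `true_mean_<group>`
#'   column per group), and `samples` (sample_name/group layout).
#' @export
simulate_polya_table <- function(design) {
  if (!inherits(design, "simulation_design")) {
    stop_validation("`design` must come from simulation_design().")
  }
  set.seed(design$seed)
  nf <- design$n_features
  feature_id <- sprintf("t%04d", seq_len(nf))
  gene_id <- sprintf("g%04d", ceiling(seq_len(nf) / design$transcripts_per_gene))
  base_mean <- if (design$vary_baseline) {
    stats::runif(nf, design$baseline_mean - 20, design$baseline_mean + 20)
  } else {
    rep(design$baseline_mean, nf)
  }
  affected <- seq_len(nf) <= design$n_affected

  samples <- tibble(
    sample_name = unlist(purrr::map(design$groups, function(g) {
      paste0(g, "_", seq_len(design$n_samples_per_group))
    })),
    group = rep(design$groups, each = design$n_samples_per_group)
  )

  true_means <- matrix(base_mean, nrow = nf, ncol = length(design$groups),
                       dimnames = list(feature_id, design$groups))
  for (g in names(design$shift)) {
    true_means[affected, g] <- true_means[affected, g] + design$shift[[g]]
  }

  recs <- purrr::pmap(samples, function(sample_name, group) {
    n_reads <- design$reads_per_feature
    lens <- unlist(purrr::map(seq_len(nf), function(i) {
      draw_lengths(n_reads, true_means[i, group], design$baseline_sd,
                   design$family)
    }))
    tibble(
      read_id = paste0(sample_name, "_r", seq_len(nf * n_reads)),
      transcript_id = rep(feature_id, each = n_reads),
      polyA_length = lens,
      sample_name = sample_name,
      group = group
    )
  })
  polya <- dplyr::bind_rows(recs)

  # plant duplicated / multi-mapped read ids: same molecule, extra transcript
  extra_frac <- design$duplicate_fraction + design$multimap_fraction
  if (extra_frac > 0) {
    u <- stats::runif(nrow(polya))
    dup_rows <- which(u < design$duplicate_fraction)
    multi_rows <- which(u >= design$duplicate_fraction & u < extra_frac)
    other_transcript <- function(rows, copies) {
      rep_rows <- rep(rows, each = copies)
      out <- polya[rep_rows, , drop = FALSE]
      idx <- match(out$transcript_id, feature_id)
      out$transcript_id <- feature_id[(idx %% nf) + 1L]
      out
    }
    polya <- dplyr::bind_rows(
      polya,
      if (length(dup_rows)) other_transcript(dup_rows, 1L),
      if (length(multi_rows)) other_transcript(multi_rows, 2L)
    ) |>
      arrange(match(.data$sample_name, samples$sample_name),
              .data$read_id)
  }
  polya$gene_id <- gene_id[match(polya$transcript_id, feature_id)]

  direction <- rep("none", nf)
  if (design$n_affected > 0) {
    net <- vapply(seq_len(nf), function(i) {
      mean(true_means[i, -1]) - true_means[i, 1]
    }, numeric(1))
    direction[affected & net > 0] <- "expansion"
    direction[affected & net < 0] <- "collapsed"
  }
  truth <- tibble(feature_id = feature_id, gene_id = gene_id,
                  affected = affected, direction = direction)
  for (g in design$groups) {
    truth[[paste0("true_mean_", g)]] <- unname(true_means[, g])
  }
  list(polya = polya, truth = truth, samples = samples)
}

#' Write a poly(A) table as a tagged BAM file
#'
#' The inverse of [extract_polya()]: each record becomes an alignment whose
#' tail length is stored in an integer auxiliary tag. The first occurrence
#' of a read id (in table order) is written as a primary alignment; later
#' occurrences become secondary alignments, mirroring a multi-assigned read.
#' Records are given a dummy 50 nt sequence — the tail estimate lives only
#' in the tag, as in basecaller output. The SAM text is converted to BAM
#' with [Rsamtools::asBam()].
#'
#' @param table A poly(A) table (typically one sample's records).
#' @param references Reference transcripts: a character vector of ids
#'   (lengths default to 1000 nt) or a data frame with columns
#'   `transcript_id`, `length`. Defaults to the transcripts present in
#'   `table`.
#' @param path Output BAM path (".bam" appended if missing).
#' @param tag Two-character tag name (default `"pt"`).
#' @param drop_tag_for Read ids written without the tail tag (to exercise
#'   `tag_missing` accounting downstream).
#' @param unmapped_read_ids Read ids written as unmapped records.
#' @return The BAM path, invisibly.
#' @export
write_synthetic_bam <- function(table, references = NULL, path, tag = "pt",
                                drop_tag_for = character(),
                                unmapped_read_ids = character()) {
  assert_polya_table(table)
  if (is.null(references)) {
    references <- unique(table$transcript_id)
  }
  if (is.character(references)) {
    references <- tibble(transcript_id = references, length = 1000L)
  }
  assert_columns(references, c("transcript_id", "length"), arg = "references")
  mapped <- !table$read_id %in% unmapped_read_ids
  unknown <- setdiff(unique(table$transcript_id[mapped]),
                     references$transcript_id)
  if (length(unknown) > 0) {
    stop_validation(sprintf("Transcript(s) not in references: %s.",
                            paste(unknown, collapse = ", ")))
  }
  if (any(references$length < 50)) {
    stop_validation("Reference lengths must be >= 50 nt (dummy read length).")
  }
  path <- sub("\\.bam$", "", path)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", references$transcript_id,
            as.integer(references$length))
  )
  dummy_seq <- strrep("A", 50)
  dummy_qual <- strrep("I", 50)
  n <- nrow(table)
  lines <- character(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    rid <- table$read_id[i]
    tag_field <- if (rid %in% drop_tag_for) "" else
      sprintf("\t%s:i:%d", tag, as.integer(table$polyA_length[i]))
    if (!mapped[i]) {
      lines[i] <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s%s",
                          rid, dummy_seq, dummy_qual, tag_field)
      next
    }
    key <- paste0(table$sample_name[i], "\r", rid)
    first <- is.null(seen[[key]])
    seen[[key]] <- TRUE
    flag <- if (first) 0L else 256L
    seq_f <- if (first) dummy_seq else "*"
    qual_f <- if (first) dummy_qual else "*"
    mapq <- if (first) 60L else 0L
    lines[i] <- sprintf("%s\t%d\t%s\t1\t%d\t50M\t*\t0\t0\t%s\t%s%s",
                        rid, flag, table$transcript_id[i], mapq,
                        seq_f, qual_f, tag_field)
  }
  sam <- paste0(path, ".sam")
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, path, overwrite = TRUE,
                          indexDestination = FALSE)
  unlink(sam)
  invisible(bam)
}

#' Write a full synthetic experiment to disk
#'
#' Materialises a simulation as the on-disk inputs the extraction pipeline
#' expects: one tagged BAM per sample, a samples CSV, a GTF mapping the
#' simulated transcripts to genes, and the truth table.
#'
#' @param design A [simulation_design()].
#' @param out_dir Output directory (created if needed).
#' @param tag Tail-length tag name.
#' @return A list with `samples_csv`, `bam_paths`, `gtf`, `truth_tsv`,
#'   `truth`, `samples` and the simulated `polya` table.
#' @export
write_synthetic_experiment <- function(design, out_dir, tag = "pt") {
  sim <- simulate_polya_table(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- tibble(transcript_id = sim$truth$feature_id, length = 1000L)
  bam_paths <- purrr::map_chr(seq_len(nrow(sim$samples)), function(i) {
    s <- sim$samples$sample_name[i]
    write_synthetic_bam(
      filter(sim$polya, .data$sample_name == s),
      references = refs,
      path = file.path(out_dir, paste0(s, ".bam")),
      tag = tag
    )
  })
  samples <- mutate(sim$samples, bam_path = bam_paths, .before = 1)
  samples_csv <- file.path(out_dir, "samples.csv")
  readr::write_csv(samples, samples_csv, progress = FALSE)
  gtf <- file.path(out_dir, "transcripts.gtf")
  write_synthetic_gtf(
    dplyr::distinct(sim$truth[, c("feature_id", "gene_id")]) |>
      rename(transcript_id = "feature_id"),
    gtf
  )
  truth_tsv <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth_tsv, progress = FALSE)
  list(samples_csv = samples_csv, bam_paths = bam_paths, gtf = gtf,
       truth_tsv = truth_tsv, truth = sim$truth, samples = samples,
       polya = sim$polya)
}

#' Write a transcript-to-gene map as a minimal GTF
#'
#' @param map Data frame with columns `transcript_id`, `gene_id`.
#' @param path Output GTF path.
#' @param source Source field (column 2).
#' @return `path`, invisibly.
#' @export
write_synthetic_gtf <- function(map, path, source = "polytail_sim") {
  assert_data_frame(map)
  assert_columns(map, c("transcript_id", "gene_id"), arg = "map")
  lines <- sprintf(
    "%s\t%s\ttranscript\t1\t1000\t.\t+\t.\ttranscript_id \"%s\"; gene_id \"%s\";",
    map$transcript_id, source, map$transcript_id, map$gene_id
  )
  writeLines(c("# synthetic annotation", lines), path)
  invisible(path)
}
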