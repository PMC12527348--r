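# In-code fixtures: small tables and files built at test time.

make_polya <- function(read_id, transcript_id, polyA_length,
                       sample_name = "s1", group = "CTR", gene_id = NULL) {
  out <- tibble::tibble(
    read_id = read_id, transcript_id = transcript_id,
    polyA_length = as.integer(polyA_length),
    sample_name = sample_name, group = group
  )
  if (!is.null(gene_id)) out$gene_id <- gene_id
  out
}

write_temp_samples_csv <- function(rows, sep = ",", ext = ".csv",
                                   header = c("bam_path", "sample_name", "group")) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(c(paste(header, collapse = sep),
               vapply(rows, paste, "", collapse = sep)), path)
  path
}

write_temp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_line <- function(tx, gene, feature = "transcript", quoted = TRUE) {
  attrs <- if (quoted) {
    sprintf('transcript_id "%s"; gene_id "%s";', tx, gene)
  } else {
    sprintf("transcript_id %s; gene_id %s;", tx, gene)
  }
  paste("chr1", "test", feature, "1", "100", ".", "+", ".", attrs, sep = "\t")
}

# Simulated two-group table without touching disk.
quick_sim <- function(n_features = 20, n_affected = 0, shift = 20,
                      sd = 10, reads = 30, samples_per_group = 1,
                      groups = c("CTR", "HIGH"), seed = 1, ...) {
  design <- polytail::simulation_design(
    n_features = n_features, groups = groups,
    n_samples_per_group = samples_per_group, reads_per_feature = reads,
    baseline_sd = sd, n_affected = n_affected, shift = shift, seed = seed,
    ...
  )
  polytail::simulate_polya_table(design)
}
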