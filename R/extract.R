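# BAM flag bits used for the alignment filter policy.
FLAG_UNMAPPED <- 4L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' Extract per-read poly(A) tail lengths from tagged BAM files
#'
#' Scans every BAM in the samples table and emits one record per alignment
#' that passes the filter policy and carries a positive integer value in the
#' tail-length auxiliary tag (dorado's `--estimate-poly-a` writes the `pt`
#' tag). The transcript assignment of a read is the reference sequence its
#' alignment points at; reads are never re-assigned between transcripts here.
#'
#' Alignments that do not yield a record are counted per skip reason:
#' `unmapped`, `filtered_by_policy` (secondary/supplementary under the
#' `"primary"` policy), `tag_missing`, and `tag_nonpositive`. Emitted rows
#' plus skipped alignments always add up to the number of alignments scanned;
#' the accounting is available via [skip_report()].
#'
#' @param samples A samples table (see [read_samples_table()]), or any data
#'   frame with columns `bam_path`, `sample_name`, `group`.
#' @param tag Two-character name of the integer auxiliary tag holding the
#'   tail-length estimate. Default `"pt"`.
#' @param policy `"primary"` (default): keep mapped primary alignments only,
#'   one tail estimate per molecule; `"all"`: also keep secondary and
#'   supplementary alignments (multi-assigned reads are then handled by the
#'   duplicate-handling functions downstream).
#'
#' @return A tibble with columns `read_id`, `transcript_id`, `polyA_length`,
#'   `sample_name`, `group`, in stable order (samples in table order, BAM
#'   record order within a sample). Attributes `tag`, `policy` and
#'   `skip_report` record provenance.
#' @seealso [skip_report()], [attach_gene_ids()], [write_synthetic_bam()]
#' @export
extract_polya <- function(samples, tag = "pt", policy = c("primary", "all")) {
  policy <- match.arg(policy)
  assert_data_frame(samples)
  assert_columns(samples, c("bam_path", "sample_name", "group"), arg = "samples")
  if (!is.character(tag) || length(tag) != 1 || nchar(tag) != 2) {
    stop_validation("`tag` must be a single two-character BAM tag name.")
  }

  per_sample <- purrr::pmap(
    samples[, c("bam_path", "sample_name", "group")],
    function(bam_path, sample_name, group) {
      scan_one_bam(bam_path, sample_name, group, tag = tag, policy = policy)
    }
  )

  records <- dplyr::bind_rows(purrr::map(per_sample, "records"))
  skips <- dplyr::bind_rows(purrr::map(per_sample, "skips"))
  if (nrow(records) == 0) {
    records <- tibble(
      read_id = character(), transcript_id = character(),
      polyA_length = integer(), sample_name = character(), group = character()
    )
  }
  attr(records, "tag") <- tag
  attr(records, "policy") <- policy
  attr(records, "skip_report") <- skips
  records
}

scan_one_bam <- function(bam_path, sample_name, group, tag, policy) {
  if (!file.exists(bam_path)) {
    stop_io(sprintf("BAM file '%s' does not exist.", bam_path))
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"), tag = tag)
  scan <- tryCatch(
    Rsamtools::scanBam(bam_path, param = param)[[1]],
    error = function(e) {
      stop_io(sprintf("Failed to read BAM file '%s': %s", bam_path,
                      conditionMessage(e)))
    }
  )
  qname <- scan$qname
  flag <- scan$flag
  rname <- as.character(scan$rname)
  tagval <- scan$tag[[tag]]
  n <- length(qname)
  if (is.null(tagval)) tagval <- rep(NA_integer_, n)
  if (!is.numeric(tagval)) {
    stop_format(sprintf(
      "Tag '%s' in '%s' is not numeric (type %s).", tag, bam_path, typeof(tagval)
    ))
  }
  if (any(is.finite(tagval) & tagval != round(tagval))) {
    stop_format(sprintf(
      "Tag '%s' in '%s' holds non-integer values.", tag, bam_path
    ))
  }

  # classify each alignment exactly once, in precedence order
  unmapped <- bitwAnd(flag, FLAG_UNMAPPED) > 0L
  nonprimary <- bitwAnd(flag, FLAG_SECONDARY) > 0L |
    bitwAnd(flag, FLAG_SUPPLEMENTARY) > 0L
  filtered <- !unmapped & (policy == "primary") & nonprimary
  considered <- !unmapped & !filtered
  tag_missing <- considered & is.na(tagval)
  tag_nonpositive <- considered & !is.na(tagval) & tagval < 1
  keep <- considered & !is.na(tagval) & tagval >= 1

  records <- tibble(
    read_id = qname[keep],
    transcript_id = rname[keep],
    polyA_length = as.integer(tagval[keep]),
    sample_name = sample_name,
    group = group
  )
  skips <- tibble(
    sample_name = sample_name,
    bam_path = bam_path,
    scanned = n,
    emitted = sum(keep),
    unmapped = sum(unmapped),
    filtered_by_policy = sum(filtered),
    tag_missing = sum(tag_missing),
    tag_nonpositive = sum(tag_nonpositive)
  )
  list(records = records, skips = skips)
}

#' Per-BAM skip accounting of an extraction
#'
#' @param polya A table returned by [extract_polya()].
#' @return A tibble with one row per scanned BAM: alignments scanned, records
#'   emitted, and counts skipped as `unmapped`, `filtered_by_policy`,
#'   `tag_missing`, `tag_nonpositive`.
#' @export
skip_report <- function(polya) {
  rep <- attr(polya, "skip_report")
  if (is.null(rep)) {
    stop_validation("No skip report attached; was this table made by extract_polya()?")
  }
  rep
}

#' Write a poly(A) table (or any result tibble) to TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polya_tsv <- function(x, path) {
  assert_data_frame(x)
  drop <- vapply(x, is.list, logical(1))
  readr::write_tsv(x[, !drop, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Read a poly(A) table written by [write_polya_tsv()]
#'
#' @param path Path to a TSV with at least the core poly(A) columns.
#' @return A tibble.
#' @export
read_polya_tsv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File '%s' does not exist.", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("polyA_length" %in% names(x)) {
    x$polyA_length <- as.integer(x$polyA_length)
  }
  x
}
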