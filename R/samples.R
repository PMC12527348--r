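#' Read an experiment design (samples table)
#'
#' The samples table maps each BAM file to a sample name and an experimental
#' group. It drives [extract_polya()]: every alignment extracted from a BAM is
#' labelled with that file's `sample_name` and `group`.
#'
#' @param path Path to a delimited text file with (case-insensitive, any
#'   order) columns `bam_path`, `sample_name`, `group`.
#' @param dialect `"auto"` (default; decided by file extension, `.tsv`/`.txt`
#'   means tab), `"csv"` or `"tsv"`.
#' @param check_paths If `TRUE` (default), error when a listed BAM file does
#'   not exist.
#'
#' @return A tibble with columns `bam_path`, `sample_name`, `group`, one row
#'   per sample. Group sizes are reported as a message.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("bam_path,sample_name,group", "a.bam,s1,CTR", "b.bam,s2,HIGH"), tf)
#' read_samples_table(tf, check_paths = FALSE)
#' @export
read_samples_table <- function(path, dialect = c("auto", "csv", "tsv"),
                               check_paths = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_io(sprintf("Samples table '%s' does not exist.", path))
  }
  if (file.size(path) == 0) {
    stop_validation(sprintf("Samples table '%s' is empty.", path))
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  names(raw) <- tolower(names(raw))
  validate_samples_table(raw, check_paths = check_paths)
}

#' Validate a samples table
#'
#' @param samples A data frame with columns `bam_path`, `sample_name`, `group`.
#' @inheritParams read_samples_table
#' @return The validated samples table as a tibble.
#' @export
validate_samples_table <- function(samples, check_paths = TRUE) {
  assert_data_frame(samples)
  assert_columns(samples, c("bam_path", "sample_name", "group"), arg = "samples")
  samples <- as_tibble(samples)[, c("bam_path", "sample_name", "group")]
  if (nrow(samples) == 0) {
    stop_validation("Samples table has no rows.")
  }
  if (anyNA(samples)) {
    stop_validation("Samples table contains missing values.")
  }
  dup <- samples$sample_name[duplicated(samples$sample_name)]
  if (length(dup) > 0) {
    stop_validation(sprintf(
      "Duplicate sample_name%s: %s.", if (length(dup) > 1) "s" else "",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (check_paths) {
    missing_bam <- samples$bam_path[!file.exists(samples$bam_path)]
    if (length(missing_bam) > 0) {
      stop_io(sprintf("BAM file(s) not found: %s.",
                      paste(missing_bam, collapse = ", ")))
    }
  }
  sizes <- dplyr::count(samples, .data$group, name = "n_samples")
  inform(paste0(
    "Samples table: ", nrow(samples), " sample(s) in ", nrow(sizes),
    " group(s) [", paste0(sizes$group, ": ", sizes$n_samples, collapse = ", "), "]"
  ))
  samples
}
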