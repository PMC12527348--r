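#' Build a transcript-to-gene map from a GTF file
#'
#' Parses the attribute column of a GTF annotation and returns one row per
#' distinct transcript with its gene identifier. Both common attribute
#' dialects are accepted (`key "value";` as written by stringtie/Ensembl and
#' the unquoted `key value;` variant). A transcript appearing on many lines
#' (exons etc.) with a consistent gene maps once; a transcript claimed by two
#' different genes is a conflict and raises an error naming the offenders.
#'
#' @param gtf_path Path to a GTF file (9 tab-separated columns).
#' @param transcript_attr Name of the attribute holding transcript ids
#'   (default `"transcript_id"`).
#' @param gene_attr Name of the attribute holding gene ids (default
#'   `"gene_id"`).
#' @return A tibble with columns `transcript_id`, `gene_id`; attributes
#'   `transcript_attr`/`gene_attr` record the source attribute names.
#' @export
parse_gtf_transcript_gene_map <- function(gtf_path,
                                          transcript_attr = "transcript_id",
                                          gene_attr = "gene_id") {
  if (!file.exists(gtf_path)) {
    stop_io(sprintf("GTF file '%s' does not exist.", gtf_path))
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop_io(sprintf("Failed to parse GTF '%s': %s",
                                        gtf_path, conditionMessage(e)))
  )
  meta <- as.data.frame(gr@elementMetadata)
  for (a in c(transcript_attr, gene_attr)) {
    if (!a %in% names(meta)) {
      stop_config(sprintf(
        "Attribute '%s' was not found on any line of '%s'.", a, gtf_path
      ))
    }
  }
  map <- tibble(
    transcript_id = as.character(meta[[transcript_attr]]),
    gene_id = as.character(meta[[gene_attr]])
  )
  map <- dplyr::filter(
    map,
    !is.na(.data$transcript_id), .data$transcript_id != "",
    !is.na(.data$gene_id), .data$gene_id != ""
  )
  if (nrow(map) == 0) {
    stop_config(sprintf(
      "No line of '%s' carries both '%s' and '%s'.",
      gtf_path, transcript_attr, gene_attr
    ))
  }
  map <- dplyr::distinct(map)
  conflicts <- map$transcript_id[duplicated(map$transcript_id)]
  if (length(conflicts) > 0) {
    offenders <- dplyr::filter(map, .data$transcript_id %in% conflicts)
    stop_conflict(
      paste0(
        "Transcript(s) mapped to more than one gene: ",
        paste(unique(conflicts), collapse = ", "), " [",
        paste0(offenders$transcript_id, "->", offenders$gene_id, collapse = ", "),
        "]"
      )
    )
  }
  attr(map, "transcript_attr") <- transcript_attr
  attr(map, "gene_attr") <- gene_attr
  map
}

#' Attach gene identifiers to a poly(A) table
#'
#' Left-joins the transcript-to-gene map onto the per-read table. Records
#' whose transcript is absent from the map are retained with a missing
#' `gene_id` (gene-level operations exclude them and report the count); no
#' row is added, dropped or reordered.
#'
#' @param polya A poly(A) table from [extract_polya()].
#' @param map A transcript-to-gene map from [parse_gtf_transcript_gene_map()],
#'   or any data frame with columns `transcript_id`, `gene_id`.
#' @return `polya` with a `gene_id` column; attribute `n_unmatched` counts
#'   records left without a gene id (also reported as a warning when > 0).
#' @export
attach_gene_ids <- function(polya, map) {
  assert_polya_table(polya)
  assert_data_frame(map)
  assert_columns(map, c("transcript_id", "gene_id"), arg = "map")
  if (nrow(polya) == 0) {
    stop_validation("`polya` has no rows.")
  }
  if (anyDuplicated(map$transcript_id) > 0) {
    stop_validation("`map` has duplicated transcript_id entries.")
  }
  keep_attrs <- attributes(polya)[c("tag", "policy", "skip_report")]
  out <- dplyr::left_join(
    dplyr::select(as_tibble(polya), -dplyr::any_of("gene_id")),
    as_tibble(map)[, c("transcript_id", "gene_id")],
    by = "transcript_id"
  )
  stopifnot(nrow(out) == nrow(polya))
  n_unmatched <- sum(is.na(out$gene_id))
  if (n_unmatched > 0) {
    warn(sprintf("%d record(s) have no gene mapping and keep a missing gene_id.",
                 n_unmatched))
  }
  for (a in names(keep_attrs)) {
    if (!is.null(keep_attrs[[a]])) attr(out, a) <- keep_attrs[[a]]
  }
  attr(out, "n_unmatched") <- n_unmatched
  out
}
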