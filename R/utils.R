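# Shared validation helpers and error constructors.

stop_validation <- function(msg, ...) {
  abort(msg, class = "polytail_validation_error", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "polytail_schema_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "polytail_io_error", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "polytail_format_error", ...)
}

stop_conflict <- function(msg, ...) {
  abort(msg, class = "polytail_conflict_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "polytail_config_error", ...)
}

assert_data_frame <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    stop_validation(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
  invisible(x)
}

assert_columns <- function(x, cols, arg = deparse(substitute(x))) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf(
      "`%s` is missing required column%s: %s.",
      arg, if (length(missing_cols) > 1) "s" else "",
      paste0("'", missing_cols, "'", collapse = ", ")
    ))
  }
  invisible(x)
}

# polyA tables are plain tibbles; this checks the core column contract.
assert_polya_table <- function(polya, require_gene = FALSE,
                               arg = deparse(substitute(polya))) {
  assert_data_frame(polya, arg = arg)
  cols <- c("read_id", "transcript_id", "polyA_length", "sample_name", "group")
  if (require_gene) cols <- c(cols, "gene_id")
  assert_columns(polya, cols, arg = arg)
  invisible(polya)
}

match_level <- function(level) {
  match.arg(level, c("transcript_id", "gene_id"))
}

`%||%` <- rlang::`%||%`
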