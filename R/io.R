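# TSV interchange. Every file written by the pipeline starts with a
# comment line naming the master seed and config hash, so any output can
# be traced back to the run that produced it.

write_stamped_tsv <- function(x, path, seed = NA, config_hash = NA) {
  cat(sprintf("# pgxscreen seed=%s config=%s\n", seed, config_hash),
      readr::format_tsv(x), sep = "", file = path)
  invisible(path)
}

read_stamped_tsv <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, ...)
}

#' Read and write expression tables
#'
#' Expression TSVs are genes x cell lines with a `gene` identifier column;
#' the preprocessing state is recorded in a `# unit_state=...` comment on
#' the first line and restored on read.
#'
#' @param expr Expression tibble (see [expr_state()]).
#' @param path File path.
#' @return `read_expression_tsv()` returns the expression tibble with its
#'   `unit_state` attribute set; the writer returns `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  cat(sprintf("# unit_state=%s\n", expr_state(expr)),
      readr::format_tsv(as_tibble(expr)), sep = "", file = path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  state <- if (grepl("^# unit_state=", first)) {
    sub("^# unit_state=", "", first)
  } else {
    "fpkm"
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  set_expr_state_(out, state)
}

#' Read screen input tables
#'
#' Readers for the long-format viability table (`cell_line`, `drug`,
#' `dose_molar`, `replicate`, `viability_raw`) and the binary mutation
#' table (`cell_line` plus one 0/1 column per gene). Comment lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_viability_tsv <- function(path) {
  out <- read_stamped_tsv(path)
  need <- c("cell_line", "drug", "dose_molar", "replicate", "viability_raw")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    abort(sprintf("%s: missing viability column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  out
}

#' @rdname read_viability_tsv
#' @export
read_mutations_tsv <- function(path) {
  out <- read_stamped_tsv(path)
  if (!"cell_line" %in% names(out)) {
    abort(sprintf("%s: mutation table needs a `cell_line` column.", path))
  }
  out
}
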