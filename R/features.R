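#' Expression-matrix preprocessing state
#'
#' Expression tables move through a fixed preprocessing pipeline —
#' FPKM -> log2 -> (optional) quantile normalization -> per-gene Z-scores —
#' tracked by a `unit_state` attribute (`"fpkm"`, `"log2"`,
#' `"quantile_normalized"`, `"zscore"`). Each transform checks the state of
#' its input, so steps cannot be applied out of order.
#'
#' @param expr Expression tibble: a `gene` identifier column plus one
#'   numeric column per cell line.
#' @return `expr_state()` returns the state string (defaults to `"fpkm"`
#'   when unset).
#' @export
expr_state <- function(expr) {
  st <- attr(expr, "unit_state", exact = TRUE)
  if (is.null(st)) "fpkm" else st
}

set_expr_state_ <- function(expr, state) {
  attr(expr, "unit_state") <- state
  expr
}

check_expr_ <- function(expr, allowed, op) {
  if (!is.data.frame(expr) || !"gene" %in% names(expr)) {
    abort("Expression table must have a `gene` column.")
  }
  st <- expr_state(expr)
  if (!st %in% allowed) {
    abort(sprintf("%s expects unit_state in {%s}, got \"%s\".",
                  op, paste(allowed, collapse = ", "), st))
  }
  invisible(st)
}

expr_values_ <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  rownames(m) <- expr$gene
  m
}

expr_rebuild_ <- function(m, state) {
  out <- as_tibble(m, rownames = "gene")
  set_expr_state_(out, state)
}

#' Log2-transform an FPKM expression table
#'
#' Elementwise `log2(value + pseudocount)`. The default pseudocount of 1
#' keeps zero FPKM at zero on the log scale.
#'
#' @inheritParams expr_state
#' @param pseudocount Positive offset added before the log.
#' @return The transformed tibble, `unit_state = "log2"`.
#' @export
log2_expression <- function(expr, pseudocount = 1) {
  check_expr_(expr, "fpkm", "log2_expression()")
  stop_not_scalar(pseudocount, "pseudocount", lo = 0, lo_open = TRUE)
  m <- expr_values_(expr)
  if (any(m < 0)) abort("FPKM values must be non-negative.")
  expr_rebuild_(log2(m + pseudocount), "log2")
}

#' Quantile-normalize a log2 expression table
#'
#' Forces every cell line (column) onto the same empirical distribution:
#' the reference is the row-wise mean of the sorted columns, and tied
#' values receive the mean of the reference values over their rank span.
#' Delegates to [limma::normalizeQuantiles()], the standard microarray/
#' RNA-seq implementation of exactly this scheme.
#'
#' @inheritParams expr_state
#' @return The normalized tibble, `unit_state = "quantile_normalized"`.
#' @export
quantile_normalize <- function(expr) {
  check_expr_(expr, "log2", "quantile_normalize()")
  m <- expr_values_(expr)
  qm <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qm) <- dimnames(m)
  expr_rebuild_(qm, "quantile_normalized")
}

#' Per-gene Z-scores across cell lines
#'
#' Standardizes each gene to mean 0 and SD 1 (denominator n - 1) across
#' cell lines, which makes elastic-net weights comparable across genes.
#' Genes with SD at or below `min_sd` carry no usable signal and are
#' dropped with a message.
#'
#' @inheritParams expr_state
#' @param min_sd Non-negative variance floor; genes with `sd <= min_sd`
#'   are removed.
#' @return The standardized tibble (possibly fewer genes),
#'   `unit_state = "zscore"`.
#' @export
zscore_expression <- function(expr, min_sd = 1e-8) {
  check_expr_(expr, c("log2", "quantile_normalized"), "zscore_expression()")
  stop_not_scalar(min_sd, "min_sd", lo = 0)
  m <- expr_values_(expr)
  if (ncol(m) < 2) abort("Z-scoring needs at least 2 cell lines.")
  sds <- apply(m, 1, sd)
  keep <- sds > min_sd
  if (any(!keep)) {
    inform(sprintf("Dropping %d gene(s) with SD <= %g: %s",
                   sum(!keep), min_sd,
                   paste(head(rownames(m)[!keep], 5), collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  expr_rebuild_(z, "zscore")
}

#' Cell-lines-by-genes feature matrix
#'
#' Transposes an expression tibble into the observations-by-features
#' matrix used by the regression stage (rows = cell lines, columns =
#' genes).
#'
#' @inheritParams expr_state
#' @return A numeric matrix with cell-line rownames and gene colnames.
#' @export
features_matrix <- function(expr) {
  check_expr_(expr, c("fpkm", "log2", "quantile_normalized", "zscore"),
              "features_matrix()")
  t(expr_values_(expr))
}

#' Standard expression preprocessing pipeline
#'
#' Convenience wrapper running log2 -> (optional) quantile normalization
#' -> Z-scores in the enforced order.
#'
#' @inheritParams log2_expression
#' @inheritParams zscore_expression
#' @param quantile Apply quantile normalization between the log and
#'   Z-score steps (default `TRUE`).
#' @return Z-scored expression tibble.
#' @export
preprocess_expression <- function(expr, pseudocount = 1, quantile = TRUE,
                                  min_sd = 1e-8) {
  out <- log2_expression(expr, pseudocount)
  if (isTRUE(quantile)) out <- quantile_normalize(out)
  zscore_expression(out, min_sd)
}
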