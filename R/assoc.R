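# Mutation-stratified association tests: exact/approximate two-sided
# Wilcoxon rank-sum and two-sample Kolmogorov-Smirnov, rank/ECDF-based and
# therefore invariant to strictly monotone transforms of the data.

wilcoxon_impl_ <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks for ties
  W <- sum(rk[seq_len(n_a)])

  use_exact <- mode == "exact" || (mode == "auto" && N <= 12)
  if (use_exact) {
    if (choose(N, n_a) > 2e6) {
      abort("Exact enumeration infeasible at this sample size; use mode = \"approx\".")
    }
    cmb <- combn(N, n_a)
    sums <- colSums(matrix(rk[cmb], nrow = n_a))
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "wilcoxon_exact"
  } else {
    mu <- n_a * (N + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "wilcoxon_normal_approx"
  }
  tibble(statistic = W, p_value = p, method = method, n_a = n_a, n_b = n_b)
}

ks_stat_ <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Survival function of the Kolmogorov distribution at lam (two-sided
# asymptotic KS p-value), alternating series.
kolmogorov_sf_ <- function(lam) {
  if (lam < 1e-8) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))))
}

ks_impl_ <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  D <- ks_stat_(a, b)

  use_exact <- mode == "exact" || (mode == "auto" && n_a * n_b <= 100)
  if (use_exact) {
    if (choose(N, n_a) > 2e6) {
      abort("Exact enumeration infeasible at this sample size; use mode = \"asymptotic\".")
    }
    pooled_sorted <- sort(c(a, b))
    # boundary rows: last index of each run of tied pooled values
    bnd <- which(!duplicated(pooled_sorted, fromLast = TRUE))
    cmb <- combn(N, n_a)
    nc <- ncol(cmb)
    ind <- matrix(0, N, nc)
    ind[cbind(as.vector(cmb), rep(seq_len(nc), each = n_a))] <- 1
    for (i in 2:N) ind[i, ] <- ind[i, ] + ind[i - 1, ]  # column cumsums
    cs <- ind[bnd, , drop = FALSE]
    Dperm <- apply(abs(cs / n_a - (bnd - cs) / n_b), 2, max)
    p <- mean(Dperm >= D - 1e-12)
    method <- "ks_exact"
  } else {
    ne <- n_a * n_b / N
    p <- kolmogorov_sf_(sqrt(ne) * D)
    method <- "ks_asymptotic"
  }
  tibble(statistic = D, p_value = p, method = method, n_a = n_a, n_b = n_b)
}

pull_groups_ <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- as.character(g[keep])
  levs <- unique(g)
  if (length(levs) != 2) abort("`group` must have exactly 2 levels.")
  list(a = v[g == levs[1]], b = v[g == levs[2]], labels = levs)
}

#' Two-sided Wilcoxon rank-sum test by mutation group
#'
#' Rank-sum statistic with midranks for ties. In `"exact"` mode (the
#' default for a pooled sample of at most 12) the p-value is obtained by
#' enumerating all `choose(n_a + n_b, n_a)` group assignments of the
#' pooled ranks, so it is exact even under ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two-sided p = min(1, 2 x smaller tail).
#'
#' @param data A data frame in long format.
#' @param value,group Columns (tidy-eval) holding the measured value and
#'   the two-level grouping (e.g. mutant vs wild-type).
#' @param mode `"auto"` (exact for small samples), `"exact"`, or
#'   `"approx"`.
#' @return One-row tibble: `statistic` (rank sum of the first group),
#'   `p_value`, `method`, `n_a`, `n_b`, `group_a`, `group_b`.
#' @export
#' @examples
#' df <- data.frame(expr = c(1, 2, 3, 4), mut = c("wt", "wt", "mut", "mut"))
#' rank_sum_test(df, expr, mut)  # exact p = 1/3
rank_sum_test <- function(data, value, group,
                          mode = c("auto", "exact", "approx")) {
  g <- pull_groups_(data, {{ value }}, {{ group }})
  out <- wilcoxon_impl_(g$a, g$b, match.arg(mode))
  out$group_a <- g$labels[1]
  out$group_b <- g$labels[2]
  out
}

#' Two-sample Kolmogorov-Smirnov test by mutation group
#'
#' D is the supremum gap between the two empirical CDFs, evaluated at the
#' pooled sorted unique values (which handles ties). In `"exact"` mode
#' (default when `n_a * n_b <= 100`) the p-value enumerates all group
#' assignments of the pooled sample; otherwise the asymptotic Kolmogorov
#' distribution is used with effective size `n_a n_b / (n_a + n_b)`. The
#' asymptotic mode is coarse below about 10 observations per group; the
#' exact mode exists precisely for that regime.
#'
#' @inheritParams rank_sum_test
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return One-row tibble: `statistic` (D), `p_value`, `method`, `n_a`,
#'   `n_b`, `group_a`, `group_b`.
#' @export
#' @examples
#' df <- data.frame(auc = c(1, 3, 2, 4), mut = c("a", "a", "b", "b"))
#' ks_test_2sample(df, auc, mut)  # D = 0.5
ks_test_2sample <- function(data, value, group,
                            mode = c("auto", "exact", "asymptotic")) {
  g <- pull_groups_(data, {{ value }}, {{ group }})
  out <- ks_impl_(g$a, g$b, match.arg(mode))
  out$group_a <- g$labels[1]
  out$group_b <- g$labels[2]
  out
}

#' Marker-expression difference by mutation status
#'
#' Wilcoxon rank-sum comparison of one gene's expression between mutant
#' and wild-type lines (the expression analog of comparing CCNA2 between
#' RAS-mutant and wild-type cohorts).
#'
#' @param expr Expression tibble (any unit state) with a `gene` column.
#' @param mutations Tibble `cell_line` plus 0/1 mutation columns.
#' @param marker_gene Gene whose expression is compared.
#' @param mutation_gene Mutation column defining the groups.
#' @inheritParams rank_sum_test
#' @return One-row tibble as in [rank_sum_test()].
#' @export
expression_mutation_test <- function(expr, mutations, marker_gene,
                                     mutation_gene,
                                     mode = c("auto", "exact", "approx")) {
  if (!marker_gene %in% expr$gene) abort("`marker_gene` not in expression table.")
  if (!mutation_gene %in% names(mutations)) {
    abort("`mutation_gene` not in mutation table.")
  }
  vals <- expr_values_(expr)[marker_gene, ]
  df <- tibble(cell_line = names(vals), value = unname(vals)) %>%
    left_join(mutations[, c("cell_line", mutation_gene)], by = "cell_line") %>%
    mutate(status = ifelse(.data[[mutation_gene]] == 1, "mutant", "wild_type"))
  if (length(unique(df$status)) != 2) {
    abort("Need at least one mutant and one wild-type line.")
  }
  rank_sum_test(df, .data$value, .data$status, mode = match.arg(mode))
}

#' Drug-response shift in mutant lines
#'
#' For each drug, compares (median-centered) AUC between mutant and
#' wild-type lines by the two-sample KS test and exports the
#' cumulative-fraction curves behind the comparison. A left-shifted mutant
#' ECDF (lower AUC) means the mutation marks sensitivity. Drugs with an
#' empty group are skipped with a warning.
#'
#' @param auc AUC tibble (`cell_line`, `drug`, `auc`).
#' @param mutations Tibble `cell_line` plus 0/1 mutation columns.
#' @param gene Mutation column defining the groups.
#' @param drugs Drugs to test (default: all in `auc`).
#' @param centered Use per-drug median-centered AUC (default `TRUE`).
#' @param mode KS mode, see [ks_test_2sample()].
#' @return Tibble of class `mutant_sensitivity_report`: per drug
#'   `n_mut`, `n_wt`, `statistic`, `p_value`, `method`, `delta_median`
#'   (mutant minus wild-type median response), plus an `ecdf` list-column
#'   of cumulative-fraction tibbles (`group`, `response`, `cum_frac`).
#' @export
mutant_sensitivity_report <- function(auc, mutations, gene, drugs = NULL,
                                      centered = TRUE,
                                      mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!gene %in% names(mutations)) abort("`gene` not in mutation table.")
  tab <- median_center(auc) %>%
    mutate(response = if (centered) .data$auc_centered else .data$auc) %>%
    left_join(mutations[, c("cell_line", gene)], by = "cell_line") %>%
    mutate(status = ifelse(.data[[gene]] == 1, "mutant", "wild_type"))
  if (any(is.na(tab$status))) {
    abort("Some cell lines in the AUC table have no mutation record.")
  }
  drugs <- drugs %||% sort(unique(tab$drug))

  rows <- purrr::map(drugs, function(d) {
    sub <- tab[tab$drug == d, ]
    n_mut <- sum(sub$status == "mutant")
    n_wt <- sum(sub$status == "wild_type")
    if (n_mut == 0 || n_wt == 0) {
      warn(sprintf("Drug %s skipped: empty %s group.", d,
                   if (n_mut == 0) "mutant" else "wild-type"))
      return(NULL)
    }
    ks <- ks_impl_(sub$response[sub$status == "mutant"],
                   sub$response[sub$status == "wild_type"], mode)
    ecdf_tbl <- sub %>%
      group_by(.data$status) %>%
      arrange(.data$response, .by_group = TRUE) %>%
      mutate(cum_frac = seq_len(dplyr::n()) / dplyr::n()) %>%
      ungroup() %>%
      select(group = "status", "response", "cum_frac")
    tibble(drug = d, n_mut = n_mut, n_wt = n_wt,
           statistic = ks$statistic, p_value = ks$p_value,
           method = ks$method,
           delta_median = median(sub$response[sub$status == "mutant"]) -
             median(sub$response[sub$status == "wild_type"]),
           ecdf = list(ecdf_tbl))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(drug = character(), n_mut = integer(), n_wt = integer(),
                  statistic = numeric(), p_value = numeric(),
                  method = character(), delta_median = numeric(),
                  ecdf = list())
  }
  attr(out, "gene") <- gene
  attr(out, "centered") <- centered
  class(out) <- c("mutant_sensitivity_report", class(out))
  out
}

#' @method tidy mutant_sensitivity_report
#' @export
tidy.mutant_sensitivity_report <- function(x, ...) {
  out <- as_tibble(x) %>% select(-"ecdf")
  class(out) <- class(tibble())
  out
}
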