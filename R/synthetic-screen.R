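#' Configure a synthetic drug screen
#'
#' Bundles the dimensions and noise model of a simulated cell-line
#' pharmacological screen. Defaults mirror a mid-size gastric-cancer panel:
#' 37 cell lines treated with 75 compounds in duplicate over a 12-point
#' half-log dilution series, with a 500-gene expression background.
#'
#' Expression is modeled per gene on the log2-FPKM scale: each gene gets a
#' location drawn from N(`expression_log_mean`, 1) and per-line values drawn
#' around it with SD `expression_log_sd`, giving heavy-tailed FPKM marginals
#' after exponentiation. Viability measurement noise is additive Gaussian on
#' the fraction-of-control scale, truncated to \[0, 1.2\] (raw luminescence
#' can exceed the vehicle control).
#'
#' @param n_cell_lines,n_genes,n_drugs Positive counts.
#' @param n_replicates Wells per (line, drug, dose); screens are typically
#'   run in duplicate.
#' @param seed Integer seed; a fixed seed makes the generated screen
#'   byte-identical across runs.
#' @param expression_log_mean Location of gene-level log2-FPKM means.
#' @param expression_log_sd Per-line SD of log2 expression around the gene
#'   mean (positive).
#' @param noise_sd_viability SD of well-level viability noise, in (0, 0.2].
#' @param noise_sd_log10_ec50 SD of per-(line, drug) jitter on log10 EC50,
#'   on top of the planted expression effects.
#' @param top_dose Highest dose in molar (default 50 micromolar).
#' @param n_doses Number of dilution points (default 12).
#' @param dose_step_ratio Dilution ratio between consecutive doses
#'   (default half-log, `10^0.5`).
#' @param hill_h Hill slope shared by all simulated curves.
#' @param e_inf Residual viability at saturating dose, in \[0, 1).
#'
#' @return A list of class `screen_config`.
#' @seealso [simulate_screen()]
#' @export
screen_config <- function(n_cell_lines = 37, n_genes = 500, n_drugs = 75,
                          n_replicates = 2, seed = 1L,
                          expression_log_mean = 3, expression_log_sd = 1,
                          noise_sd_viability = 0.05,
                          noise_sd_log10_ec50 = 0.15,
                          top_dose = 50e-6, n_doses = 12,
                          dose_step_ratio = 10^0.5,
                          hill_h = 1, e_inf = 0) {
  stop_not_count(n_cell_lines, "n_cell_lines")
  stop_not_count(n_genes, "n_genes")
  stop_not_count(n_drugs, "n_drugs")
  stop_not_count(n_replicates, "n_replicates")
  stop_not_scalar(expression_log_sd, "expression_log_sd", lo = 0, lo_open = TRUE)
  stop_not_scalar(noise_sd_viability, "noise_sd_viability",
                  lo = 0, hi = 0.2, lo_open = TRUE)
  stop_not_scalar(noise_sd_log10_ec50, "noise_sd_log10_ec50", lo = 0)
  stop_not_scalar(top_dose, "top_dose", lo = 0, lo_open = TRUE)
  stop_not_count(n_doses, "n_doses")
  stop_not_scalar(dose_step_ratio, "dose_step_ratio", lo = 1, lo_open = TRUE)
  stop_not_scalar(hill_h, "hill_h", lo = 0, lo_open = TRUE)
  stop_not_scalar(e_inf, "e_inf", lo = 0, hi = 1, hi_open = TRUE)

  structure(list(
    n_cell_lines = as.integer(n_cell_lines), n_genes = as.integer(n_genes),
    n_drugs = as.integer(n_drugs), n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    noise_sd_viability = noise_sd_viability,
    noise_sd_log10_ec50 = noise_sd_log10_ec50,
    top_dose = top_dose, n_doses = as.integer(n_doses),
    dose_step_ratio = dose_step_ratio,
    hill_h = hill_h, e_inf = e_inf
  ), class = "screen_config")
}

#' Planted gene-drug effects and mutation-expression links
#'
#' `planted_effect()` declares that a marker gene's expression shifts a
#' drug's potency: per 1 SD of the marker's expression Z-score, log10 EC50
#' moves by `effect_b`. Negative `effect_b` means higher expression lowers
#' EC50 (more potent), i.e. the gene is a sensitivity marker.
#'
#' `mutation_link()` declares a mutation that drives marker expression: in
#' mutant lines the marker's log2 expression is shifted by
#' `expression_shift` (the mutant-oncogene-drives-cell-cycle-gene motif,
#' e.g. KRAS elevating CCNA2).
#'
#' @param gene,drug Identifiers present in the generated screen
#'   (genes `g0001`, ..., drugs `d001`, ..., zero-padded).
#' @param effect_b Finite real; shift in log10 EC50 per SD of marker Z.
#' @param mutation_gene,marker_gene Identifiers; `marker_gene` must be a
#'   screen gene.
#' @param expression_shift Added to the marker's log2 FPKM in mutant lines.
#' @param mutant_fraction Probability a line is mutant, strictly in (0, 1).
#'
#' @return A one-row tibble; rows can be combined with [dplyr::bind_rows()].
#' @export
planted_effect <- function(gene, drug, effect_b) {
  stop_not_scalar(effect_b, "effect_b")
  tibble(gene = as.character(gene), drug = as.character(drug),
         effect_b = as.numeric(effect_b))
}

#' @rdname planted_effect
#' @export
mutation_link <- function(mutation_gene, marker_gene, expression_shift,
                          mutant_fraction = 8 / 37) {
  stop_not_scalar(expression_shift, "expression_shift")
  stop_not_scalar(mutant_fraction, "mutant_fraction",
                  lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  tibble(mutation_gene = as.character(mutation_gene),
         marker_gene = as.character(marker_gene),
         expression_shift = as.numeric(expression_shift),
         mutant_fraction = as.numeric(mutant_fraction))
}

#' Hill viability at a given dose
#'
#' Standard sigmoidal dose-response model:
#' `v = e_inf + (1 - e_inf) / (1 + (dose/ec50)^hill_h)`,
#' monotone non-increasing in dose, equal to 1 at dose 0 and to
#' `(1 + e_inf) / 2` at `dose = ec50` when `e_inf = 0` gives 0.5.
#'
#' @param dose Non-negative dose(s), molar. Vectorized.
#' @param ec50 Positive half-maximal dose, molar.
#' @param hill_h Positive Hill slope.
#' @param e_inf Residual viability at saturating dose, in \[0, 1).
#' @return Viability fraction(s) in (`e_inf`, 1\].
#' @export
#' @examples
#' hill_viability(1e-6, ec50 = 1e-6)            # 0.5
#' hill_viability(0, ec50 = 1e-6)               # 1
hill_viability <- function(dose, ec50, hill_h = 1, e_inf = 0) {
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("`dose` must be non-negative and finite.")
  }
  stop_not_scalar(ec50, "ec50", lo = 0, lo_open = TRUE)
  stop_not_scalar(hill_h, "hill_h", lo = 0, lo_open = TRUE)
  stop_not_scalar(e_inf, "e_inf", lo = 0, hi = 1, hi_open = TRUE)
  e_inf + (1 - e_inf) / (1 + (dose / ec50)^hill_h)
}

gene_ids_ <- function(n) sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
line_ids_ <- function(n) sprintf("line%0*d", max(2L, nchar(n)), seq_len(n))
drug_ids_ <- function(n) sprintf("d%0*d", max(3L, nchar(n)), seq_len(n))

#' Simulate a complete drug screen with planted biomarkers
#'
#' Generates an expression matrix, a binary mutation table, and a
#' plate-level viability table whose structure mirrors a real cell-line
#' screen, with known ground truth. Per (line, drug), the log10 EC50 is
#' `baseline(drug) + sum(effect_b * Z(marker expression)) + jitter`, where
#' Z is the marker's expression Z-score across lines (after any mutation
#' shifts); viability at each dose follows the Hill curve plus truncated
#' Gaussian well noise. Per-drug baselines are drawn uniformly over the
#' interior of the log10 dose window so planted effects move curves
#' visibly. Duplicate wells are independent noise draws.
#'
#' @param config A [screen_config()].
#' @param effects Tibble of [planted_effect()] rows (or `NULL` for a null
#'   screen).
#' @param links Tibble of [mutation_link()] rows (or `NULL`).
#'
#' @return A list of class `screen_sim` with elements:
#' \describe{
#'   \item{expression}{tibble, `gene` column plus one column per cell line;
#'     FPKM scale (`unit_state` attribute `"fpkm"`).}
#'   \item{mutations}{tibble, `cell_line` plus one 0/1 column per mutation
#'     gene.}
#'   \item{viability}{long tibble: `cell_line`, `drug`, `dose_molar`,
#'     `replicate`, `viability_raw` (fraction-of-vehicle scale).}
#'   \item{ground_truth}{list of tibbles: `effects`, `links`,
#'     `baseline` (per-drug baseline log10 EC50), and `marker_z`
#'     (realized marker Z-scores).}
#' }
#' @export
#' @examples
#' cfg <- screen_config(n_cell_lines = 10, n_genes = 50, n_drugs = 2, seed = 7)
#' sim <- simulate_screen(cfg, effects = planted_effect("g0001", "d001", -1))
#' head(sim$viability)
simulate_screen <- function(config, effects = NULL, links = NULL) {
  if (!inherits(config, "screen_config")) {
    abort("`config` must come from screen_config().")
  }
  genes <- gene_ids_(config$n_genes)
  lines <- line_ids_(config$n_cell_lines)
  drugs <- drug_ids_(config$n_drugs)

  effects <- if (is.null(effects)) {
    tibble(gene = character(), drug = character(), effect_b = numeric())
  } else {
    as_tibble(effects)
  }
  links <- if (is.null(links)) {
    tibble(mutation_gene = character(), marker_gene = character(),
           expression_shift = numeric(), mutant_fraction = numeric())
  } else {
    as_tibble(links)
  }
  bad_g <- setdiff(c(effects$gene, links$marker_gene), genes)
  if (length(bad_g)) abort(paste0("Unknown gene id(s): ",
                                  paste(bad_g, collapse = ", ")))
  bad_d <- setdiff(effects$drug, drugs)
  if (length(bad_d)) abort(paste0("Unknown drug id(s): ",
                                  paste(bad_d, collapse = ", ")))
  if (any(!is.finite(effects$effect_b))) abort("effect_b must be finite.")

  doses <- dilution_series(config$top_dose, config$n_doses,
                           config$dose_step_ratio)$dose_molar

  with_seed_(config$seed, {
    # --- expression: per-gene location, per-line spread, on log2 scale
    mu_g <- rnorm(config$n_genes, config$expression_log_mean, 1)
    log2_expr <- matrix(
      rnorm(config$n_genes * config$n_cell_lines,
            mean = rep(mu_g, times = config$n_cell_lines),
            sd = config$expression_log_sd),
      nrow = config$n_genes, ncol = config$n_cell_lines,
      dimnames = list(genes, lines)
    )

    # --- mutations and their expression shifts
    mut_genes <- unique(links$mutation_gene)
    mut_status <- matrix(0L, nrow = config$n_cell_lines,
                         ncol = length(mut_genes),
                         dimnames = list(lines, mut_genes))
    for (mg in mut_genes) {
      frac <- links$mutant_fraction[match(mg, links$mutation_gene)]
      mut_status[, mg] <- rbinom(config$n_cell_lines, 1L, frac)
    }
    if (nrow(links)) {
      for (k in seq_len(nrow(links))) {
        carriers <- mut_status[, links$mutation_gene[k]] == 1L
        log2_expr[links$marker_gene[k], carriers] <-
          log2_expr[links$marker_gene[k], carriers] + links$expression_shift[k]
      }
    }

    # --- per-(line, drug) log10 EC50
    window <- sort(log10(range(doses)))
    margin <- min(1.5, diff(window) / 4)
    baseline <- runif(config$n_drugs, window[1] + margin, window[2] - margin)
    names(baseline) <- drugs

    l10_ec50 <- matrix(rep(baseline, each = config$n_cell_lines),
                       nrow = config$n_cell_lines, ncol = config$n_drugs,
                       dimnames = list(lines, drugs))
    eff_genes <- unique(effects$gene)
    marker_z <- NULL
    if (length(eff_genes)) {
      zmat <- t(apply(log2_expr[eff_genes, , drop = FALSE], 1,
                      function(x) (x - mean(x)) / sd(x)))
      rownames(zmat) <- eff_genes
      marker_z <- as_tibble(zmat, rownames = "gene") %>%
        tidyr::pivot_longer(-"gene", names_to = "cell_line",
                            values_to = "z")
      for (k in seq_len(nrow(effects))) {
        l10_ec50[, effects$drug[k]] <- l10_ec50[, effects$drug[k]] +
          effects$effect_b[k] * zmat[effects$gene[k], ]
      }
    }
    l10_ec50 <- l10_ec50 + matrix(
      rnorm(length(l10_ec50), 0, config$noise_sd_log10_ec50),
      nrow = nrow(l10_ec50))

    # --- plate wells, deterministic order: drug > line > dose > replicate
    grid <- tidyr::expand_grid(
      drug = drugs, cell_line = lines, dose_molar = doses,
      replicate = seq_len(config$n_replicates)
    )
    ec50_vec <- 10^l10_ec50[cbind(match(grid$cell_line, lines),
                                  match(grid$drug, drugs))]
    v_true <- config$e_inf + (1 - config$e_inf) /
      (1 + (grid$dose_molar / ec50_vec)^config$hill_h)
    grid$viability_raw <- clip(
      v_true + rnorm(nrow(grid), 0, config$noise_sd_viability), 0, 1.2)

    expression <- as_tibble(2^log2_expr, rownames = "gene")
    attr(expression, "unit_state") <- "fpkm"
    mutations <- as_tibble(mut_status, rownames = "cell_line")

    structure(list(
      expression = expression,
      mutations = mutations,
      viability = grid[, c("cell_line", "drug", "dose_molar",
                           "replicate", "viability_raw")],
      ground_truth = list(
        effects = effects, links = links,
        baseline = tibble(drug = drugs, baseline_log10_ec50 = unname(baseline)),
        marker_z = marker_z
      )
    ), class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(
    "<screen_sim>  %d cell lines x %d genes x %d drugs; %d viability wells\n",
    ncol(x$expression) - 1L, nrow(x$expression),
    length(unique(x$viability$drug)), nrow(x$viability)))
  if (nrow(x$ground_truth$effects)) {
    cat("planted effects:\n")
    print(x$ground_truth$effects)
  } else {
    cat("no planted effects (null screen)\n")
  }
  invisible(x)
}
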