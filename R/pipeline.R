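#' Configure an end-to-end screen analysis
#'
#' Bundles everything [run_screen_analysis()] needs: either a simulation
#' block (a [screen_config()] plus optional planted effects/links) or
#' paths to expression/viability/mutation TSVs, the elastic-net settings,
#' and the biomarker-calling policy. A single master seed fans out to
#' per-stage substreams (simulation, CV folds, per-drug bootstraps), so
#' stages are independently reproducible.
#'
#' @param simulate Optional [screen_config()]; when present the screen is
#'   simulated instead of read from disk (its seed is overridden by
#'   `seed`).
#' @param effects,links Planted structure for the simulation block.
#' @param expression_path,viability_path,mutation_path Input TSVs when not
#'   simulating (`mutation_path` optional).
#' @param enet An [enet_config()] (its seed is derived from `seed`).
#' @param n_bootstrap Bootstrap resamples per drug.
#' @param freq_threshold Selection-frequency threshold for calls.
#' @param weight_cutoff Per-drug cutoff policy, see [call_biomarkers()].
#' @param weight_quantile Quantile for the default cutoff policy.
#' @param quantile_normalize Quantile-normalize expression before
#'   Z-scoring (default `TRUE`).
#' @param assoc_genes Mutation columns to test against drug response
#'   (default: all columns of the mutation table).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing files.
#' @param seed Master integer seed.
#' @param verbose Emit log lines (timestamp, level, stage, message).
#' @return A list of class `screen_analysis_config`.
#' @export
screen_analysis_config <- function(simulate = NULL, effects = NULL,
                                   links = NULL,
                                   expression_path = NULL,
                                   viability_path = NULL,
                                   mutation_path = NULL,
                                   enet = enet_config(),
                                   n_bootstrap = 200L,
                                   freq_threshold = 0.75,
                                   weight_cutoff = NULL,
                                   weight_quantile = 0.90,
                                   quantile_normalize = TRUE,
                                   assoc_genes = NULL,
                                   out_dir = NULL, seed = 1L,
                                   verbose = TRUE) {
  if (is.null(simulate) &&
      (is.null(expression_path) || is.null(viability_path))) {
    abort("Provide either a `simulate` block or expression + viability paths.")
  }
  if (!is.null(simulate) && !inherits(simulate, "screen_config")) {
    abort("`simulate` must come from screen_config().")
  }
  structure(list(
    simulate = simulate, effects = effects, links = links,
    expression_path = expression_path, viability_path = viability_path,
    mutation_path = mutation_path, enet = enet,
    n_bootstrap = as.integer(n_bootstrap),
    freq_threshold = freq_threshold, weight_cutoff = weight_cutoff,
    weight_quantile = weight_quantile,
    quantile_normalize = isTRUE(quantile_normalize),
    assoc_genes = assoc_genes, out_dir = out_dir,
    seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "screen_analysis_config")
}

config_hash_ <- function(cfg) {
  stable <- cfg[setdiff(names(cfg), c("out_dir", "verbose"))]
  rlang::hash(stable)
}

#' Validate a screen input bundle
#'
#' Structural checks on the three tables: identifier overlap between
#' expression, viability and mutation tables, duplicated identifiers and
#' wells, and per-drug dose-grid consistency (constant dilution ratio).
#' Content problems are reported as diagnostics, never thrown.
#'
#' @param expression Expression tibble (`gene` column + cell lines).
#' @param viability Long well table.
#' @param mutations Optional mutation tibble.
#' @return A tibble of diagnostics (`check`, `detail`); zero rows means
#'   the bundle is consistent.
#' @export
validate_screen_inputs <- function(expression, viability, mutations = NULL) {
  diags <- list()
  note <- function(check, detail) {
    diags[[length(diags) + 1]] <<- tibble(check = check, detail = detail)
  }

  expr_lines <- setdiff(names(expression), "gene")
  via_lines <- unique(viability$cell_line)
  for (l in setdiff(via_lines, expr_lines)) {
    note("line_missing_expression",
         sprintf("cell line %s has viability data but no expression column", l))
  }
  for (l in setdiff(expr_lines, via_lines)) {
    note("line_missing_viability",
         sprintf("cell line %s has expression but no viability data", l))
  }
  dup_g <- unique(expression$gene[duplicated(expression$gene)])
  for (g in dup_g) note("duplicated_gene", sprintf("gene %s appears more than once", g))

  dup_wells <- viability %>%
    dplyr::count(.data$cell_line, .data$drug, .data$dose_molar,
                 .data$replicate) %>%
    filter(.data$n > 1)
  if (nrow(dup_wells)) {
    note("duplicated_wells",
         sprintf("%d well(s) recorded more than once", nrow(dup_wells)))
  }

  # dose grids: within each drug the sorted unique doses must form a
  # geometric series (constant consecutive ratio)
  for (d in sort(unique(viability$drug))) {
    doses <- sort(unique(viability$dose_molar[viability$drug == d]),
                  decreasing = TRUE)
    if (length(doses) >= 3) {
      ratios <- doses[-length(doses)] / doses[-1]
      if (max(ratios) / min(ratios) > 1 + 1e-6) {
        note("irregular_dose_grid",
             sprintf("drug %s has a non-constant dilution ratio", d))
      }
    }
  }

  if (!is.null(mutations)) {
    for (l in setdiff(unique(mutations$cell_line), expr_lines)) {
      note("line_missing_expression",
           sprintf("cell line %s in mutation table has no expression column", l))
    }
    for (l in setdiff(expr_lines, unique(mutations$cell_line))) {
      note("line_missing_mutations",
           sprintf("cell line %s has no mutation record", l))
    }
  }

  if (!length(diags)) {
    tibble(check = character(), detail = character())
  } else {
    bind_rows(diags)
  }
}

#' Run the full biomarker-discovery pipeline
#'
#' Simulate (or load) the screen, compute per-(line, drug) AUC values and
#' their median-centered view, preprocess expression to Z-scores, run
#' per-drug cross-validated elastic-net stability selection, call
#' biomarkers, and test mutation-stratified drug response. With an
#' `out_dir` set, all result tables are written as TSV (each stamped with
#' the seed and config hash) together with a `manifest.json`; rerunning
#' with the same config yields byte-identical files.
#'
#' @param cfg A [screen_analysis_config()].
#' @return A list of class `screen_analysis` with elements `auc`,
#'   `stability`, `calls`, `assoc` (list of
#'   [mutant_sensitivity_report()] per mutation gene), `expression_tests`,
#'   `diagnostics`, `manifest`, and `screen` (the input bundle).
#' @export
run_screen_analysis <- function(cfg) {
  if (!inherits(cfg, "screen_analysis_config")) {
    abort("`cfg` must come from screen_analysis_config().")
  }
  hash <- config_hash_(cfg)
  vb <- cfg$verbose
  log_line("setup", sprintf("seed=%d config=%s", cfg$seed, hash), verbose = vb)

  # --- inputs
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    sim_cfg$seed <- substream_seed(cfg$seed, 0L, stream = 10L)
    log_line("simulate", sprintf(
      "%d lines x %d genes x %d drugs", sim_cfg$n_cell_lines,
      sim_cfg$n_genes, sim_cfg$n_drugs), verbose = vb)
    screen <- simulate_screen(sim_cfg, cfg$effects, cfg$links)
    expression <- screen$expression
    viability <- screen$viability
    mutations <- if (ncol(screen$mutations) > 1) screen$mutations else NULL
    ground_truth <- screen$ground_truth
  } else {
    log_line("load", cfg$viability_path, verbose = vb)
    expression <- read_expression_tsv(cfg$expression_path)
    viability <- read_viability_tsv(cfg$viability_path)
    mutations <- if (!is.null(cfg$mutation_path)) {
      read_mutations_tsv(cfg$mutation_path)
    } else {
      NULL
    }
    ground_truth <- NULL
  }

  diagnostics <- validate_screen_inputs(expression, viability, mutations)
  if (nrow(diagnostics)) {
    log_line("validate", sprintf("%d diagnostic(s); first: %s",
                                 nrow(diagnostics), diagnostics$detail[1]),
             level = "WARN", verbose = vb)
  }

  # --- dose response
  log_line("auc", "computing per-(line, drug) AUC", verbose = vb)
  auc <- auc_scores(viability) %>% median_center()

  # --- features
  log_line("features", sprintf("log2 -> %sZ-scores",
                               if (cfg$quantile_normalize) "quantile -> " else ""),
           verbose = vb)
  z <- preprocess_expression(expression, quantile = cfg$quantile_normalize)
  X <- features_matrix(z)
  X <- X[sort(intersect(rownames(X), unique(auc$cell_line))), , drop = FALSE]
  auc_used <- auc %>% filter(.data$cell_line %in% rownames(X))

  # --- stability selection and calls
  enet_cfg <- cfg$enet
  enet_cfg$seed <- substream_seed(cfg$seed, 0L, stream = 20L)
  log_line("select", sprintf("stability selection, B=%d per drug",
                             cfg$n_bootstrap), verbose = vb)
  stability <- stability_select_drugs(X, auc_used, enet_cfg,
                                      n_bootstrap = cfg$n_bootstrap)
  calls <- call_biomarkers(stability, cfg$freq_threshold,
                           cfg$weight_cutoff, cfg$weight_quantile)
  log_line("select", sprintf("%d biomarker call(s)", nrow(calls)), verbose = vb)

  # --- mutation associations
  assoc <- list()
  expression_tests <- NULL
  if (!is.null(mutations) && ncol(mutations) > 1) {
    genes <- cfg$assoc_genes %||% setdiff(names(mutations), "cell_line")
    for (g in genes) {
      if (length(unique(mutations[[g]])) < 2) next
      log_line("assoc", sprintf("KS drug-response report for %s", g),
               verbose = vb)
      assoc[[g]] <- mutant_sensitivity_report(auc_used, mutations, g)
    }
    if (!is.null(ground_truth) && nrow(ground_truth$links)) {
      expression_tests <- purrr::pmap_dfr(
        ground_truth$links[, c("mutation_gene", "marker_gene")],
        function(mutation_gene, marker_gene) {
          if (length(unique(mutations[[mutation_gene]])) < 2) return(NULL)
          expression_mutation_test(expression, mutations, marker_gene,
                                   mutation_gene) %>%
            mutate(mutation_gene = mutation_gene, marker_gene = marker_gene)
        })
    }
  }

  manifest <- list(
    package = "pgxscreen",
    version = as.character(utils::packageVersion("pgxscreen")),
    seed = cfg$seed, config_hash = hash,
    n_cell_lines = nrow(X), n_genes = ncol(X),
    n_drugs = length(unique(auc_used$drug)),
    n_bootstrap = cfg$n_bootstrap, freq_threshold = cfg$freq_threshold,
    n_calls = nrow(calls)
  )

  result <- structure(list(
    auc = auc, stability = stability, calls = calls, assoc = assoc,
    expression_tests = expression_tests, diagnostics = diagnostics,
    manifest = manifest,
    screen = list(expression = expression, viability = viability,
                  mutations = mutations, ground_truth = ground_truth)
  ), class = "screen_analysis")

  if (!is.null(cfg$out_dir)) {
    write_analysis_outputs(result, cfg$out_dir, seed = cfg$seed,
                           config_hash = hash, verbose = vb)
  }
  result
}

#' Write the result bundle of a screen analysis
#'
#' @param result A `screen_analysis` object.
#' @param out_dir Directory (created if needed).
#' @param seed,config_hash Stamped into every file header.
#' @param verbose Log the files written.
#' @return `out_dir`, invisibly.
#' @export
write_analysis_outputs <- function(result, out_dir, seed = NA,
                                   config_hash = NA, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    write_stamped_tsv(x, file.path(out_dir, name), seed, config_hash)
    log_line("write", name, verbose = verbose)
  }
  w(result$auc, "auc.tsv")
  w(tidy(result$stability), "stability.tsv")
  w(tidy_calls_(result$calls), "biomarker_calls.tsv")
  if (length(result$assoc)) {
    tests <- purrr::imap_dfr(result$assoc, function(r, g) {
      tidy(r) %>% mutate(mutation_gene = g, .before = 1)
    })
    w(tests, "mutation_response_tests.tsv")
    ecdfs <- purrr::imap_dfr(result$assoc, function(r, g) {
      tidyr::unnest(as_tibble(r)[, c("drug", "ecdf")], "ecdf") %>%
        mutate(mutation_gene = g, .before = 1)
    })
    w(ecdfs, "mutation_response_ecdf.tsv")
  }
  if (!is.null(result$expression_tests) && nrow(result$expression_tests)) {
    w(result$expression_tests, "expression_mutation_tests.tsv")
  }
  if (nrow(result$diagnostics)) w(result$diagnostics, "diagnostics.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("write", "manifest.json", verbose = verbose)
  invisible(out_dir)
}

tidy_calls_ <- function(calls) {
  out <- as_tibble(calls)
  class(out) <- class(tibble())
  out
}

#' Write the tables of a simulated screen
#'
#' @param screen A `screen_sim` bundle from [simulate_screen()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_tsv <- function(screen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(screen$expression,
                       file.path(out_dir, "expression.tsv"))
  readr::write_tsv(screen$mutations, file.path(out_dir, "mutations.tsv"))
  readr::write_tsv(screen$viability, file.path(out_dir, "viability.tsv"))
  gt <- screen$ground_truth
  readr::write_tsv(gt$effects, file.path(out_dir, "ground_truth_effects.tsv"))
  readr::write_tsv(gt$links, file.path(out_dir, "ground_truth_links.tsv"))
  readr::write_tsv(gt$baseline, file.path(out_dir, "ground_truth_baseline.tsv"))
  invisible(out_dir)
}

#' @export
print.screen_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<screen_analysis> %d lines x %d genes x %d drugs | B=%d\n",
              m$n_cell_lines, m$n_genes, m$n_drugs, m$n_bootstrap))
  cat(sprintf("seed=%d config=%s\n", m$seed, m$config_hash))
  cat(sprintf("%d biomarker call(s):\n", nrow(x$calls)))
  if (nrow(x$calls)) print(tidy_calls_(x$calls))
  invisible(x)
}
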