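gs <- function(a, b) {
  data.frame(v = c(a, b), g = rep(c("a", "b"), c(length(a), length(b))))
}

test_that("exact Wilcoxon p-values match full enumeration", {
  expect_equal(rank_sum_test(gs(c(1, 2), c(3, 4)), v, g)$p_value, 1 / 3)
  expect_equal(rank_sum_test(gs(1:3, 4:6), v, g)$p_value, 0.1)
  expect_equal(rank_sum_test(gs(c(5, 5, 7), c(5, 5, 7)), v, g)$p_value, 1)
  out <- rank_sum_test(gs(c(1, 2), c(3, 4)), v, g)
  expect_equal(out$method, "wilcoxon_exact")
  expect_equal(out$statistic, 3)  # rank sum of group a
  expect_error(rank_sum_test(gs(numeric(0), 1:3), v, g), "2 levels")
})

test_that("exact modes reproduce base R on tie-free samples", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(rank_sum_test(gs(a, b), v, g, mode = "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(ks_test_2sample(gs(a, b), v, g, mode = "exact")$p_value,
                 suppressWarnings(ks.test(a, b, exact = TRUE)$p.value))
  }
})

test_that("KS D is the ECDF supremum gap, ties included", {
  expect_equal(ks_test_2sample(gs(c(1, 3), c(2, 4)), v, g)$statistic, 0.5)
  ident <- ks_test_2sample(gs(1:4, 1:4), v, g)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  sep <- ks_test_2sample(gs(1:4, 5:8), v, g)
  expect_equal(sep$statistic, 1)
  tied <- ks_test_2sample(gs(c(1, 1, 2), c(1, 2, 2)), v, g)
  expect_equal(tied$statistic, 1 / 3)
})

test_that("both tests are invariant to monotone transforms and label swaps", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 1)
    p_w <- rank_sum_test(gs(a, b), v, g)$p_value
    p_k <- ks_test_2sample(gs(a, b), v, g)$p_value
    expect_equal(rank_sum_test(gs(exp(a), exp(b)), v, g)$p_value, p_w)
    expect_equal(ks_test_2sample(gs(exp(a), exp(b)), v, g)$p_value, p_k)
    expect_equal(rank_sum_test(gs(b, a), v, g)$p_value, p_w)
    expect_equal(ks_test_2sample(gs(b, a), v, g)$p_value, p_k)
  }
})

test_that("approximate modes track the exact distributions at n = 6 + 6", {
  set.seed(14)
  wmax <- kmax <- 0
  for (i in 1:100) {
    d <- gs(rnorm(6), rnorm(6))
    wmax <- max(wmax, abs(rank_sum_test(d, v, g, mode = "exact")$p_value -
                            rank_sum_test(d, v, g, mode = "approx")$p_value))
    kmax <- max(kmax, abs(ks_test_2sample(d, v, g, mode = "exact")$p_value -
                            ks_test_2sample(d, v, g, mode = "asymptotic")$p_value))
  }
  # tie-corrected normal approximation is tight for the rank sum
  expect_lt(wmax, 0.02)
  # the Kolmogorov limit is coarser on a 6+6 lattice (the exact mode is
  # the default at this size); its observed error stays below 0.06
  expect_lt(kmax, 0.06)
})

test_that("the tie-corrected normal approximation matches base R's", {
  set.seed(15)
  for (i in 1:20) {
    a <- sample(1:4, 6, TRUE); b <- sample(1:4, 6, TRUE)
    pa <- rank_sum_test(gs(a, b), v, g, mode = "approx")$p_value
    pr <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(pa, pr, tolerance = 1e-12)
  }
})

test_that("expression-by-mutation testing wires groups correctly", {
  sim <- simulate_screen(
    screen_config(n_cell_lines = 30, n_genes = 20, n_drugs = 1, seed = 21),
    links = mutation_link("KRAS", "g0002", expression_shift = 3,
                          mutant_fraction = 0.4))
  out <- expression_mutation_test(sim$expression, sim$mutations,
                                  "g0002", "KRAS")
  expect_lt(out$p_value, 0.01)   # planted 3-log2 shift is unmissable
  expect_setequal(c(out$group_a, out$group_b), c("mutant", "wild_type"))
  null_out <- expression_mutation_test(sim$expression, sim$mutations,
                                       "g0010", "KRAS")
  expect_gt(null_out$p_value, 0.001)
  expect_error(expression_mutation_test(sim$expression, sim$mutations,
                                        "nope", "KRAS"), "marker_gene")
})

test_that("mutant-sensitivity reports detect a planted mutation-drug link", {
  link <- mutation_link("KRAS", "g0001", expression_shift = 2,
                        mutant_fraction = 0.35)
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_screen(
      screen_config(n_cell_lines = 40, n_genes = 30, n_drugs = 1, seed = s),
      effects = planted_effect("g0001", "d001", -1), links = link)
    auc <- auc_scores(sim$viability)
    rep <- mutant_sensitivity_report(auc, sim$mutations, "KRAS")
    hits <- hits + (rep$p_value[rep$drug == "d001"] < 0.05 &&
                      rep$delta_median < 0)
  }
  expect_gte(hits, 4)
})

test_that("a report with no mutant lines is empty and warned about", {
  sim <- simulate_screen(screen_config(n_cell_lines = 10, n_genes = 10,
                                       n_drugs = 2, seed = 3))
  auc <- auc_scores(sim$viability)
  muts <- tibble::tibble(cell_line = unique(auc$cell_line), KRAS = 0L)
  w <- capture_warnings(rep <- mutant_sensitivity_report(auc, muts, "KRAS"))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2)   # one per drug
  expect_equal(nrow(rep), 0)
})

test_that("ECDF columns integrate to the full cumulative range", {
  link <- mutation_link("KRAS", "g0001", expression_shift = 1,
                        mutant_fraction = 0.3)
  sim <- simulate_screen(screen_config(n_cell_lines = 20, n_genes = 10,
                                       n_drugs = 1, seed = 8), links = link)
  auc <- auc_scores(sim$viability)
  rep <- mutant_sensitivity_report(auc, sim$mutations, "KRAS")
  ec <- rep$ecdf[[1]]
  expect_setequal(unique(ec$group), c("mutant", "wild_type"))
  expect_equal(max(ec$cum_frac[ec$group == "mutant"]), 1)
  expect_equal(max(ec$cum_frac[ec$group == "wild_type"]), 1)
  td <- tidy(rep)
  expect_false("ecdf" %in% names(td))
})
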