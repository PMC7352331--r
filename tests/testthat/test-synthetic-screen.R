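test_that("hill_viability matches the sigmoid closed form and its limits", {
  expect_equal(hill_viability(1e-6, ec50 = 1e-6), 0.5)
  expect_equal(hill_viability(0, ec50 = 1e-6), 1)
  expect_equal(hill_viability(100e-6, ec50 = 1e-6, hill_h = 1), 1 / 101)
  expect_equal(hill_viability(1e-6, ec50 = 1e-6, e_inf = 0.2), 0.6)
  # monotone non-increasing in dose
  d <- dilution_series(50e-6, 12)$dose_molar
  for (h in c(0.5, 1, 2)) {
    v <- hill_viability(sort(d), ec50 = 1e-7, hill_h = h)
    expect_true(all(diff(v) <= 0))
  }
  expect_error(hill_viability(-1e-6, ec50 = 1e-6), "non-negative")
  expect_error(hill_viability(1e-6, ec50 = 0), "ec50")
})

test_that("a fixed seed reproduces the screen exactly; config is validated", {
  cfg <- screen_config(n_cell_lines = 8, n_genes = 30, n_drugs = 2, seed = 42)
  eff <- planted_effect("g0002", "d001", -0.5)
  s1 <- simulate_screen(cfg, effects = eff)
  s2 <- simulate_screen(cfg, effects = eff)
  expect_identical(s1$viability, s2$viability)
  expect_identical(s1$expression, s2$expression)
  s3 <- simulate_screen(screen_config(n_cell_lines = 8, n_genes = 30,
                                      n_drugs = 2, seed = 43), effects = eff)
  expect_false(identical(s1$viability, s3$viability))

  expect_error(screen_config(n_cell_lines = 0), "positive integer")
  expect_error(screen_config(noise_sd_viability = 0.5), "noise_sd_viability")
  expect_error(simulate_screen(cfg, effects = planted_effect("nope", "d001", -1)),
               "Unknown gene")
  expect_error(simulate_screen(cfg, effects = planted_effect("g0001", "zzz", -1)),
               "Unknown drug")
})

test_that("viability wells live on the truncated fraction scale", {
  sim <- simulate_screen(screen_config(n_cell_lines = 12, n_genes = 20,
                                       n_drugs = 3, seed = 5))
  expect_true(all(sim$viability$viability_raw >= 0))
  expect_true(all(sim$viability$viability_raw <= 1.2))
  # duplicate wells are distinct noise draws
  reps <- tidyr::pivot_wider(sim$viability, names_from = "replicate",
                             values_from = "viability_raw")
  expect_false(all(reps$`1` == reps$`2`))
})

test_that("a null screen has no systematic gene-AUC correlation", {
  mean_cors <- vapply(1:20, function(s) {
    sim <- simulate_screen(screen_config(n_cell_lines = 20, n_genes = 500,
                                         n_drugs = 1, seed = s))
    auc <- auc_scores(sim$viability)
    X <- features_matrix(preprocess_expression(sim$expression, quantile = FALSE))
    y <- auc$auc[match(rownames(X), auc$cell_line)]
    mean(cor(X, y))
  }, numeric(1))
  expect_lt(abs(mean(mean_cors)), 0.05)
})

test_that("a strong planted effect drives a near-deterministic marker-AUC link", {
  for (s in 1:3) {
    cfg <- screen_config(n_cell_lines = 40, n_genes = 50, n_drugs = 1,
                         noise_sd_viability = 0.02, seed = s)
    sim <- simulate_screen(cfg, effects = planted_effect("g0001", "d001", -1))
    auc <- auc_scores(sim$viability)
    mz <- sim$ground_truth$marker_z
    z <- mz$z[match(auc$cell_line, mz$cell_line)]
    expect_lt(cor(z, auc$auc), -0.8)
  }
})

test_that("larger planted effects give larger marker-AUC correlations", {
  mean_abs_cor <- vapply(c(-0.25, -0.5, -1), function(b) {
    cors <- vapply(1:5, function(s) {
      cfg <- screen_config(n_cell_lines = 30, n_genes = 30, n_drugs = 1,
                           seed = s)
      sim <- simulate_screen(cfg, effects = planted_effect("g0001", "d001", b))
      auc <- auc_scores(sim$viability)
      mz <- sim$ground_truth$marker_z
      cor(mz$z[match(auc$cell_line, mz$cell_line)], auc$auc)
    }, numeric(1))
    mean(abs(cors))
  }, numeric(1))
  expect_true(all(diff(mean_abs_cor) > 0))
})

test_that("mutation links shift marker expression by the stated log2 amount", {
  shift <- 1.5
  link <- mutation_link("KRAS", "g0003", expression_shift = shift,
                        mutant_fraction = 0.4)
  diffs <- ses <- numeric(8)
  for (s in 1:8) {
    sim <- simulate_screen(screen_config(n_cell_lines = 40, n_genes = 20,
                                         n_drugs = 1, seed = s),
                           links = link)
    l2 <- log2(as.matrix(sim$expression[sim$expression$gene == "g0003",
                                        -1, drop = FALSE]))
    mut <- sim$mutations$KRAS[match(colnames(l2), sim$mutations$cell_line)] == 1
    diffs[s] <- mean(l2[mut]) - mean(l2[!mut])
    ses[s] <- sqrt(var(l2[mut]) / sum(mut) + var(l2[!mut]) / sum(!mut))
  }
  # mutant-vs-wild-type log2 gap recovers the planted shift within 2 SE
  expect_lt(abs(mean(diffs) - shift), 2 * mean(ses) / sqrt(8))
})
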