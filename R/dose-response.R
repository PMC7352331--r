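#' Geometric dilution series
#'
#' Builds the descending dose grid of a serial-dilution assay:
#' `dose[k] = top / step_ratio^(k-1)`. The default is a 12-point half-log
#' series from 50 micromolar, the usual design for multi-dose cytotoxicity
#' screens.
#'
#' @param top Highest dose (molar), positive.
#' @param n_points Number of doses, at least 1.
#' @param step_ratio Ratio between consecutive doses, must exceed 1
#'   (half-log = `10^0.5`).
#' @return A tibble with `dose_index` (1 = top dose) and `dose_molar`,
#'   descending.
#' @export
#' @examples
#' dilution_series(50e-6, 12)
dilution_series <- function(top = 50e-6, n_points = 12,
                            step_ratio = 10^0.5) {
  stop_not_scalar(top, "top", lo = 0, lo_open = TRUE)
  stop_not_count(n_points, "n_points")
  stop_not_scalar(step_ratio, "step_ratio", lo = 1, lo_open = TRUE)
  tibble(dose_index = seq_len(n_points),
         dose_molar = top / step_ratio^(seq_len(n_points) - 1))
}

#' Normalize raw viability to vehicle control
#'
#' Divides raw well readings by the mean vehicle-control (e.g. DMSO)
#' signal and clips the ratio to \[0, 1\]; readings above control are
#' treated as full viability.
#'
#' @param raw Raw viability reading(s).
#' @param vehicle_mean Positive mean of the vehicle-control wells.
#' @return Viability fraction(s) in \[0, 1\].
#' @export
normalize_viability <- function(raw, vehicle_mean) {
  stop_not_scalar(vehicle_mean, "vehicle_mean", lo = 0, lo_open = TRUE)
  clip(raw / vehicle_mean, 0, 1)
}

#' Trapezoidal AUC of one viability curve on the log-dose axis
#'
#' Integrates viability over log10(dose) by the trapezoidal rule and
#' divides by the log10 dose span, so the result is unit-free on \[0, 1\]
#' and a flat curve at viability v returns exactly v. Lower AUC means the
#' line is more sensitive to the drug. Invariant to rescaling all doses by
#' a constant.
#'
#' @param dose_molar Strictly monotone positive doses (any order, but
#'   strictly increasing or decreasing), length >= 2.
#' @param viability Viability fractions, same length.
#' @return AUC scalar in \[0, 1\] (for viability in \[0, 1\]).
#' @export
#' @examples
#' d <- dilution_series(50e-6, 12)$dose_molar
#' auc_trapezoid(d, rep(1, 12))  # flat curve -> 1
auc_trapezoid <- function(dose_molar, viability) {
  if (length(dose_molar) < 2) abort("Need at least 2 dose points.")
  if (length(dose_molar) != length(viability)) {
    abort("`dose_molar` and `viability` lengths differ.")
  }
  if (any(dose_molar <= 0)) abort("Doses must be positive.")
  u <- log10(dose_molar)
  du <- diff(u)
  if (!(all(du > 0) || all(du < 0))) {
    abort("Doses must be strictly monotone.")
  }
  if (du[1] < 0) {  # integrate on the ascending axis
    u <- rev(u); viability <- rev(viability); du <- diff(u)
  }
  sum(du * (head(viability, -1) + viability[-1]) / 2) / (u[length(u)] - u[1])
}

#' Replicate-averaged, vehicle-normalized viability curves
#'
#' Collapses a long well table to one curve per (cell line, drug):
#' replicate wells are averaged on the raw scale, then normalized to the
#' vehicle mean and clipped to \[0, 1\]. A (line, drug) pair missing any of
#' that drug's dose points is dropped with a warning rather than imputed.
#'
#' @param viability Long tibble with columns `cell_line`, `drug`,
#'   `dose_molar`, `replicate`, `viability_raw`.
#' @param vehicle_mean Mean vehicle-control signal used for normalization
#'   (the simulator emits data already on the fraction-of-vehicle scale, so
#'   its curves use the default 1).
#' @return Tibble `cell_line`, `drug`, `dose_molar`, `viability`, doses
#'   descending within each curve.
#' @export
viability_curves <- function(viability, vehicle_mean = 1) {
  need <- c("cell_line", "drug", "dose_molar", "replicate", "viability_raw")
  miss <- setdiff(need, names(viability))
  if (length(miss)) abort(paste0("Missing viability columns: ",
                                 paste(miss, collapse = ", ")))
  stop_not_scalar(vehicle_mean, "vehicle_mean", lo = 0, lo_open = TRUE)

  curves <- viability %>%
    group_by(.data$cell_line, .data$drug, .data$dose_molar) %>%
    summarise(viability = mean(.data$viability_raw), .groups = "drop") %>%
    mutate(viability = normalize_viability(.data$viability, vehicle_mean))

  # drop pairs that do not cover the drug's full dose grid
  n_dose <- curves %>%
    distinct(.data$drug, .data$dose_molar) %>%
    dplyr::count(.data$drug, name = "n_grid")
  bad <- curves %>%
    dplyr::count(.data$cell_line, .data$drug, name = "n_obs") %>%
    left_join(n_dose, by = "drug") %>%
    filter(.data$n_obs < .data$n_grid)
  if (nrow(bad)) {
    warn(sprintf("Dropping %d (cell line, drug) pair(s) with missing dose points: %s",
                 nrow(bad),
                 paste(paste(bad$cell_line, bad$drug, sep = "/"),
                       collapse = ", ")))
    curves <- curves %>%
      dplyr::anti_join(bad, by = c("cell_line", "drug"))
  }
  curves %>% arrange(.data$cell_line, .data$drug, dplyr::desc(.data$dose_molar))
}

#' Per-(cell line, drug) AUC scores
#'
#' Applies [auc_trapezoid()] to each curve of a well table (or a
#' pre-assembled curve table from [viability_curves()]).
#'
#' @param viability Long well table (`viability_raw` present) or curve
#'   table (`viability` present).
#' @param vehicle_mean Passed to [viability_curves()] when starting from
#'   raw wells.
#' @return Tibble `cell_line`, `drug`, `auc`.
#' @export
#' @examples
#' sim <- simulate_screen(screen_config(n_cell_lines = 6, n_genes = 20,
#'                                      n_drugs = 2, seed = 1))
#' auc_scores(sim$viability)
auc_scores <- function(viability, vehicle_mean = 1) {
  curves <- if ("viability_raw" %in% names(viability)) {
    viability_curves(viability, vehicle_mean)
  } else {
    viability
  }
  curves %>%
    group_by(.data$cell_line, .data$drug) %>%
    summarise(auc = auc_trapezoid(.data$dose_molar, .data$viability),
              .groups = "drop")
}

#' Median-center AUC values per drug
#'
#' Subtracts the per-drug median AUC across cell lines, the usual display
#' scale for screen heat maps and for mutation-stratified response
#' comparisons. Centering is idempotent and every drug's centered median is
#' exactly 0.
#'
#' @param auc Tibble with `cell_line`, `drug`, `auc`.
#' @return The input with an `auc_centered` column added (replaced if
#'   present).
#' @export
median_center <- function(auc) {
  miss <- setdiff(c("cell_line", "drug", "auc"), names(auc))
  if (length(miss)) abort(paste0("Missing AUC columns: ",
                                 paste(miss, collapse = ", ")))
  if (!nrow(auc)) abort("Empty AUC table.")
  auc %>%
    select(-dplyr::any_of("auc_centered")) %>%
    group_by(.data$drug) %>%
    mutate(auc_centered = .data$auc - median(.data$auc)) %>%
    ungroup()
}
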