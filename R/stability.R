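#' Bootstrap stability selection for one drug
#'
#' Fixes (alpha, lambda) by full-data cross-validation, then refits the
#' elastic net on `n_bootstrap` resamples of the cell lines (with
#' replacement) and summarizes each feature by its selection frequency
#' (fraction of fits with nonzero weight, nonzero meaning `|beta| >
#' 1e-10`) and its average weight over all fits, zeros included. A
#' bootstrap sample whose response is constant carries no signal and is
#' redrawn (up to 10 retries, then skipped with a warning).
#'
#' @param X Standardized feature matrix, cell lines x genes.
#' @param y Response vector (AUC per cell line).
#' @param cfg An [enet_config()]; `cfg$seed` drives fold assignment and
#'   the bootstrap resamples.
#' @param n_bootstrap Number of resamples (default 200).
#' @param drug Label recorded in the result (default `"y"`).
#' @param refit_cv Re-run hyperparameter cross-validation inside every
#'   bootstrap sample instead of fixing (alpha, lambda) once
#'   (substantially slower; default `FALSE`).
#' @param mean_over_selected Average weights over the fits where the
#'   feature was selected, instead of over all fits (default `FALSE`).
#' @return A tibble of class `stability_result` with columns `drug`,
#'   `gene`, `mean_weight`, `frequency`, `n_bootstrap`; attributes
#'   `alpha`, `lambda` record the fixed hyperparameters.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
#' y <- -X[, 1] + rnorm(20, sd = 0.2)
#' cfg <- enet_config(alpha_grid = c(0.5, 1), n_lambda = 30,
#'                    n_cv_iterations = 2, n_folds = 5, seed = 1)
#' stability_select(X, y, cfg, n_bootstrap = 25)
stability_select <- function(X, y, cfg = enet_config(), n_bootstrap = 200L,
                             drug = "y", refit_cv = FALSE,
                             mean_over_selected = FALSE) {
  X <- check_xy_(X, y)
  stop_not_count(n_bootstrap, "n_bootstrap")
  p <- ncol(X)
  cv <- enet_cv(X, y, cfg)

  beta_mat <- matrix(0, nrow = p, ncol = n_bootstrap)
  used <- logical(n_bootstrap)

  with_seed_(substream_seed(cfg$seed, 0L, stream = 1L), {
    for (b in seq_len(n_bootstrap)) {
      idx <- NULL
      for (try in 1:10) {
        cand <- sample(nrow(X), replace = TRUE)
        if (var(y[cand]) > 0) { idx <- cand; break }
        log_line("bootstrap", sprintf(
          "resample %d draw %d had constant response; redrawing", b, try),
          level = "WARN", verbose = FALSE)
      }
      if (is.null(idx)) {
        warn(sprintf("Bootstrap %d skipped: constant response in 10 draws.", b))
        next
      }
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      if (refit_cv) {
        cfg_b <- cfg
        cfg_b$seed <- substream_seed(cfg$seed, b, stream = 2L)
        cv_b <- enet_cv(Xb, yb, cfg_b)
        a <- cv_b$alpha; lam_target <- cv_b$lambda
      } else {
        a <- cv$alpha; lam_target <- cv$lambda
      }
      # warm-started descent from the sample's own lambda_max to the target
      lmax_b <- lambda_max(Xb, yb, a)
      lam_seq <- if (lmax_b > lam_target) {
        exp(seq(log(lmax_b), log(lam_target), length.out = 20))
      } else {
        lam_target
      }
      fit <- enet_path_fit(Xb, yb, a, lam_seq,
                           tol = cfg$tol, max_iter = cfg$max_iter)
      beta_mat[, b] <- fit$beta[, length(lam_seq)]
      used[b] <- TRUE
    }
  })

  nz <- abs(beta_mat) > 1e-10
  n_used <- sum(used)
  denom_freq <- max(n_used, 1L)
  freq <- rowSums(nz[, used, drop = FALSE]) / denom_freq
  mw <- if (mean_over_selected) {
    sel_counts <- rowSums(nz[, used, drop = FALSE])
    ifelse(sel_counts > 0,
           rowSums(beta_mat[, used, drop = FALSE]) / pmax(sel_counts, 1L), 0)
  } else {
    rowSums(beta_mat[, used, drop = FALSE]) / denom_freq
  }

  out <- tibble(drug = drug,
                gene = colnames(X) %||% paste0("x", seq_len(p)),
                mean_weight = unname(mw), frequency = unname(freq),
                n_bootstrap = n_used)
  attr(out, "alpha") <- cv$alpha
  attr(out, "lambda") <- cv$lambda
  class(out) <- c("stability_result", class(out))
  out
}

#' Stability selection across all drugs of a screen
#'
#' Runs [stability_select()] once per drug of an AUC table, deriving each
#' drug's RNG substream from the master seed and the drug's index so that
#' adding a drug never perturbs the others.
#'
#' @param X Standardized feature matrix (cell lines x genes); rownames
#'   must match `auc$cell_line`.
#' @param auc AUC tibble (`cell_line`, `drug`, `auc`).
#' @inheritParams stability_select
#' @return A combined `stability_result` tibble; per-drug (alpha, lambda)
#'   in the `hyperparams` attribute.
#' @export
stability_select_drugs <- function(X, auc, cfg = enet_config(),
                                   n_bootstrap = 200L, refit_cv = FALSE,
                                   mean_over_selected = FALSE) {
  drugs <- sort(unique(auc$drug))
  res <- vector("list", length(drugs))
  hp <- vector("list", length(drugs))
  for (di in seq_along(drugs)) {
    d <- drugs[di]
    sub <- auc[auc$drug == d, ]
    yv <- sub$auc[match(rownames(X), sub$cell_line)]
    if (any(is.na(yv))) abort(sprintf(
      "AUC values missing for some cell lines of drug %s.", d))
    cfg_d <- cfg
    cfg_d$seed <- substream_seed(cfg$seed, di)
    r <- stability_select(X, yv, cfg_d, n_bootstrap = n_bootstrap,
                          drug = d, refit_cv = refit_cv,
                          mean_over_selected = mean_over_selected)
    hp[[di]] <- tibble(drug = d, alpha = attr(r, "alpha"),
                       lambda = attr(r, "lambda"))
    res[[di]] <- r
  }
  out <- bind_rows(res)
  attr(out, "hyperparams") <- bind_rows(hp)
  class(out) <- c("stability_result", class(out))
  out
}

#' Per-drug default weight cutoff
#'
#' Drugs differ greatly in the spread of their bootstrap weights, so a
#' single absolute-weight cutoff does not transfer across drugs. The
#' default policy trims each drug's own weight spectrum: the cutoff is the
#' `quantile_q` quantile (type 7) of |mean weight| among that drug's
#' frequency-passing features. With no passing features the cutoff is
#' +Inf (no calls) and a message is logged.
#'
#' @param res A `stability_result` tibble.
#' @param quantile_q Quantile in \[0, 1\] (default 0.90).
#' @param freq_threshold Selection-frequency threshold defining "passing"
#'   (strict inequality; default 0.75).
#' @return Tibble `drug`, `weight_cutoff`.
#' @export
default_weight_cutoff <- function(res, quantile_q = 0.90,
                                  freq_threshold = 0.75) {
  stop_not_scalar(quantile_q, "quantile_q", lo = 0, hi = 1)
  stop_not_scalar(freq_threshold, "freq_threshold", lo = 0, hi = 1,
                  lo_open = TRUE)
  res %>%
    as_tibble() %>%
    group_by(.data$drug) %>%
    summarise(weight_cutoff = {
      w <- abs(.data$mean_weight[.data$frequency > freq_threshold])
      if (!length(w)) {
        inform(sprintf("Drug %s: no features pass frequency > %g; cutoff = Inf.",
                       .data$drug[1], freq_threshold))
        Inf
      } else {
        unname(quantile(w, quantile_q, type = 7))
      }
    }, .groups = "drop")
}

#' Call biomarkers from a stability-selection result
#'
#' A (gene, drug) pair is called when its selection frequency strictly
#' exceeds `freq_threshold` and its |mean weight| reaches the drug's
#' weight cutoff. Direction follows the sign of the mean weight with AUC
#' as the response: positive weight means higher expression tracks higher
#' AUC (resistance marker); negative weight means sensitivity marker.
#'
#' @inheritParams default_weight_cutoff
#' @param freq_threshold Frequency threshold in (0, 1); calls require
#'   `frequency > freq_threshold` (strictly).
#' @param weight_cutoff `NULL` for the per-drug default policy
#'   ([default_weight_cutoff()] at `quantile_q`), a single non-negative
#'   number applied to every drug, or a tibble `drug`, `weight_cutoff`.
#' @param quantile_q Passed to [default_weight_cutoff()] when
#'   `weight_cutoff` is `NULL`.
#' @return Tibble of class `biomarker_calls`: `drug`, `gene`,
#'   `direction` (`"sensitivity"`/`"resistance"`), `frequency`,
#'   `mean_weight`. May be empty.
#' @export
call_biomarkers <- function(res, freq_threshold = 0.75,
                            weight_cutoff = NULL, quantile_q = 0.90) {
  stop_not_scalar(freq_threshold, "freq_threshold", lo = 0, hi = 1,
                  lo_open = TRUE)
  cutoffs <- if (is.null(weight_cutoff)) {
    default_weight_cutoff(res, quantile_q, freq_threshold)
  } else if (is.data.frame(weight_cutoff)) {
    as_tibble(weight_cutoff)
  } else {
    stop_not_scalar(weight_cutoff, "weight_cutoff", lo = 0)
    tibble(drug = unique(res$drug), weight_cutoff = weight_cutoff)
  }
  out <- res %>%
    as_tibble() %>%
    left_join(cutoffs, by = "drug") %>%
    filter(.data$frequency > freq_threshold,
           abs(.data$mean_weight) >= .data$weight_cutoff) %>%
    mutate(direction = ifelse(.data$mean_weight > 0,
                              "resistance", "sensitivity")) %>%
    select("drug", "gene", "direction", "frequency", "mean_weight") %>%
    arrange(.data$drug, dplyr::desc(abs(.data$mean_weight)))
  class(out) <- c("biomarker_calls", class(out))
  out
}

#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) {
  tibble(drug = x$drug, gene = x$gene, mean_weight = x$mean_weight,
         frequency = x$frequency, n_bootstrap = x$n_bootstrap)
}

#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble(n_drugs = length(unique(x$drug)),
         n_genes = length(unique(x$gene)),
         n_bootstrap = max(x$n_bootstrap),
         max_frequency = max(x$frequency))
}
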