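#' Mean prediction error of a prediction table
#'
#' The headline accuracy summary: mean absolute percent prediction error,
#' `MPE% = 100/N * sum |pred_i - obs_i| / obs_i`. The signed variant
#' (`100/N * sum (pred_i - obs_i)/obs_i`) is reported alongside under a
#' distinct name since either convention is found in practice.
#'
#' @param table Data frame with columns `observed` (> 0) and `predicted`.
#' @return One-row tibble: `n`, `mpe` (%), `mpe_signed` (%).
#' @export
#' @examples
#' mean_prediction_error(tibble::tibble(observed = c(1, 2), predicted = c(2, 1)))
mean_prediction_error <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("observed", "predicted") %in% names(table)))
  if (nrow(table) < 1) abort("prediction table is empty")
  bad <- which(table$observed <= 0)
  if (length(bad)) {
    abort(paste("observed concentration must be positive; offending row(s):",
                paste(bad, collapse = ", ")))
  }
  rel <- (table$predicted - table$observed) / table$observed
  tibble::tibble(n = nrow(table), mpe = 100 * mean(abs(rel)),
                 mpe_signed = 100 * mean(rel))
}

#' Tumor-to-plasma ratio summary by group and antibody
#'
#' Per (group, antibody), the mean of per-subject tumor/plasma concentration
#' ratios, rounded to two decimals for reporting; per group, the ratio of the
#' target-binding arm's mean to the non-binding arm's mean (computed from the
#' two-decimal reported means, and itself rounded to two decimals). Groups
#' missing one arm get `NA` rather than an imputed ratio.
#'
#' @param cohort Cohort tibble with `group`, `antibody`,
#'   `observed_tumor_conc`, `observed_plasma_conc`.
#' @return Tibble: `group`, `antibody`, `mean_tp_ratio`,
#'   `ratio_binding_over_nonbinding`.
#' @export
group_tp_table <- function(cohort) {
  stopifnot(all(c("group", "antibody", "observed_tumor_conc",
                  "observed_plasma_conc") %in% names(cohort)))
  if (any(cohort$observed_plasma_conc <= 0)) {
    abort("observed plasma concentrations must be positive")
  }
  means <- cohort |>
    dplyr::mutate(tp = .data$observed_tumor_conc / .data$observed_plasma_conc) |>
    dplyr::group_by(.data$group, .data$antibody) |>
    dplyr::summarise(mean_tp_ratio = round(mean(.data$tp), 2), .groups = "drop")
  tp_ratio_summary(means)
}

#' Binding/non-binding ratio from per-group mean tumor-to-plasma ratios
#'
#' Works directly from a table of reported group means (e.g. a published
#' summary table) rather than subject-level data; used by [group_tp_table()]
#' and usable standalone.
#'
#' @param means Tibble with `group`, `antibody` (`"non-binding"` /
#'   `"target-binding"`), `mean_tp_ratio`.
#' @return `means` with a `ratio_binding_over_nonbinding` column (two
#'   decimals; `NA` where an arm is missing).
#' @export
tp_ratio_summary <- function(means) {
  stopifnot(all(c("group", "antibody", "mean_tp_ratio") %in% names(means)))
  wide <- tidyr::pivot_wider(means, id_cols = "group",
                             names_from = "antibody",
                             values_from = "mean_tp_ratio")
  ratio <- if (all(c("target-binding", "non-binding") %in% names(wide))) {
    round(wide[["target-binding"]] / wide[["non-binding"]], 2)
  } else {
    rep(NA_real_, nrow(wide))
  }
  dplyr::left_join(means,
                   tibble::tibble(group = wide$group,
                                  ratio_binding_over_nonbinding = ratio),
                   by = "group")
}

#' Model-comparison table
#'
#' Collates fitted covariate structures into the standard selection table:
#' log-likelihood, AIC, delta-AIC from the best model, and MPE, sorted by AIC
#' with ties broken by fewer parameters.
#'
#' @param fits List of `covariate_fit` objects fitted to the same cohort.
#' @param predictions Optional list (same length/order) of prediction tables
#'   to compute MPE from; defaults to each fit's own training predictions.
#' @return Tibble: `structure`, `n_params`, `loglik`, `aic`, `delta_aic`,
#'   `mpe`, `mpe_signed`.
#' @export
aic_table <- function(fits, predictions = NULL) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f$cohort_n, 0)
  if (length(unique(ns)) != 1) abort("fits were evaluated on different cohorts")
  predictions <- predictions %||% lapply(fits, function(f) f$predictions)
  stopifnot(length(predictions) == length(fits))
  tab <- purrr::map2_dfr(fits, predictions, function(f, p) {
    err <- mean_prediction_error(p)
    tibble::tibble(structure = f$structure, n_params = f$n_params,
                   loglik = f$loglik, aic = f$aic,
                   mpe = err$mpe, mpe_signed = err$mpe_signed)
  })
  tab <- dplyr::arrange(tab, .data$aic, .data$n_params)
  dplyr::mutate(tab, delta_aic = .data$aic - .data$aic[1], .after = "aic")
}
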