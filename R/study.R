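#' Replicated covariate-recovery and model-selection simulation study
#'
#' The package's built-in operating-characteristics study. Each replicate
#' (i) generates a non-binding-antibody training cohort under the ground-truth
#' Ktrans covariate structure with proportional observation error,
#' (ii) fits the candidate structures to it, and (iii) generates a matched
#' target-binding cohort and predicts it a priori with each fitted model.
#' Summaries include bias and RMSE of the recovered slopes, how often AIC
#' prefers the generating structure over the covariate-free population fit,
#' and the mean prediction error of each structure on the binding arm.
#'
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + 1000 * r` derived seeds.
#' @param obs_cv Proportional observation error CV of the generated cohorts.
#' @param truth Ground-truth [covariate_model()] (Ktrans structure).
#' @param base Base [tumor_params()].
#' @param plasma_nonbinding,plasma_binding [plasma_pk()] per antibody.
#' @param structures Candidate structures to fit/evaluate; must contain
#'   `"ktrans"` and `"population"` for the AIC comparison, `"base"` is
#'   evaluated without fitting.
#' @param settings A [fit_settings()].
#' @return An object of class `covariate_study`: `$replicates` (one row per
#'   replicate x structure with theta estimates, AIC, MPE) and `$summary`
#'   (per-structure mean MPE; slope bias/RMSE in percent; AIC preference
#'   fractions).
#' @export
covariate_study <- function(n_replicates = 20, seed = 1, obs_cv = 0.2,
                            truth = true_covariate_model(),
                            base = tumor_params(),
                            plasma_nonbinding = plasma_pk(),
                            plasma_binding = plasma_pk(),
                            structures = c("base", "population", "ktrans"),
                            settings = fit_settings()) {
  stopifnot(truth$structure == "ktrans")
  noise <- noise_model(obs_cv = obs_cv)
  groups_nb <- group_phenotypes("non-binding")
  groups_tb <- group_phenotypes("target-binding")

  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    rs <- seed + 1000L * r
    nb <- generate_cohort(groups_nb, truth, base, plasma_nonbinding, noise,
                          seed = rs, antibody = "non-binding")
    tb <- generate_cohort(groups_tb, truth, base, plasma_binding, noise,
                          seed = rs + 1L, antibody = "target-binding")
    purrr::map_dfr(structures, function(st) {
      fit <- fit_population(nb, st, base, plasma_nonbinding, settings)
      pred <- predict_cohort(fit, tb, base, plasma_binding, rtol = settings$rtol)
      err <- mean_prediction_error(pred)
      tibble::tibble(
        replicate = r, structure = st,
        theta_q = if (st == "ktrans") fit$model$theta_q[1] else NA_real_,
        theta_sigma = if (st == "ktrans") fit$model$theta_sigma[1] else NA_real_,
        loglik = fit$loglik, aic = fit$aic,
        mpe_train = mean_prediction_error(fit$predictions)$mpe,
        mpe_binding = err$mpe
      )
    })
  })

  wide_aic <- tidyr::pivot_wider(reps[c("replicate", "structure", "aic")],
                                 names_from = "structure", values_from = "aic")
  wide_mpe <- tidyr::pivot_wider(reps[c("replicate", "structure", "mpe_binding")],
                                 names_from = "structure", values_from = "mpe_binding")
  kt <- dplyr::filter(reps, .data$structure == "ktrans")
  rel_q <- kt$theta_q / truth$theta_q[1] - 1
  rel_s <- kt$theta_sigma / truth$theta_sigma[1] - 1

  summary <- list(
    n_replicates = n_replicates,
    theta_q_bias_pct = 100 * mean(rel_q),
    theta_q_rmse_pct = 100 * sqrt(mean(rel_q^2)),
    theta_sigma_bias_pct = 100 * mean(rel_s),
    theta_sigma_rmse_pct = 100 * sqrt(mean(rel_s^2)),
    aic_ktrans_le_population = mean(wide_aic$ktrans <= wide_aic$population),
    aic_ktrans_best = mean(wide_aic$ktrans < wide_aic$population),
    mean_mpe = vapply(structures, function(st) mean(wide_mpe[[st]]), 0)
  )
  structure(list(replicates = reps, summary = summary, truth = truth,
                 obs_cv = obs_cv),
            class = "covariate_study")
}

#' @export
print.covariate_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<covariate_study> %d replicates, obs CV = %g\n",
              s$n_replicates, x$obs_cv))
  cat(sprintf("  theta_q: bias %+.1f%%, RMSE %.1f%% | theta_sigma: bias %+.1f%%, RMSE %.1f%%\n",
              s$theta_q_bias_pct, s$theta_q_rmse_pct,
              s$theta_sigma_bias_pct, s$theta_sigma_rmse_pct))
  cat(sprintf("  AIC(ktrans) <= AIC(population) in %.0f%% of replicates\n",
              100 * s$aic_ktrans_le_population))
  cat("  mean MPE on the binding arm (%):\n")
  print(round(s$mean_mpe, 1))
  invisible(x)
}

#' Patlak fitting performance under signal noise
#'
#' Simulates `n_tumors` DCE experiments at a fixed protocol with proportional
#' SPGR signal noise, runs the full signal-to-concentration + Patlak pipeline
#' on each, and summarizes the recovery of Ktrans and Vp.
#'
#' @param n_tumors Number of simulated tumors.
#' @param true_ktrans,true_vp Generating parameters.
#' @param signal_cv Proportional signal noise CV.
#' @param protocol An [acq_protocol()].
#' @param seed Integer seed.
#' @param t10 True pre-contrast T1 (ms).
#' @return A list with `$fits` (tibble of per-tumor estimates) and `$summary`
#'   (median relative bias and IQR of Ktrans and Vp, in percent).
#' @export
patlak_noise_study <- function(n_tumors = 200, true_ktrans = 0.02,
                               true_vp = 0.05, signal_cv = 0.05,
                               protocol = acq_protocol(), seed = 1,
                               t10 = 2000) {
  noise <- noise_model(dce_signal_cv = signal_cv, aif_variability = 0.15)
  fits <- purrr::map_dfr(seq_len(n_tumors), function(i) {
    aif <- generate_aif(i, protocol, noise, seed = seed + 2L * i)
    sig <- generate_dce_observation(true_ktrans, true_vp, aif, t10, protocol,
                                    noise, seed = seed + 2L * i + 1L)
    ct <- signal_to_concentration(sig, t10, protocol)
    fit <- patlak_fit(ct, aif, fit_window = c(protocol$injection_time, Inf))
    tibble::tibble(tumor = i, ktrans = fit$ktrans, vp = fit$vp)
  })
  rel_k <- fits$ktrans / true_ktrans - 1
  rel_v <- if (true_vp > 0) fits$vp / true_vp - 1 else rep(NA_real_, n_tumors)
  list(
    fits = fits,
    summary = list(
      ktrans_median_bias_pct = 100 * median(rel_k),
      ktrans_iqr_pct = 100 * stats::IQR(rel_k),
      vp_median_bias_pct = 100 * median(rel_v)
    )
  )
}
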