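test_that("covariate equations: arithmetic, limits, and bounds on sigma_v", {
  base <- tumor_params()

  # 1/(1 + theta x): theta = 100 min at Ktrans = 0.01/min halves sigma
  m <- covariate_model("ktrans", theta_q = 3.3e-3, theta_sigma = 100)
  p <- apply_covariates(m, ktrans = 0.01, vp = 0, base)
  expect_equal(p$sigma_v, 0.5)
  expect_equal(p$q_tu, 3.3e-5)

  # zero sigma slope: fully reflective wall (sigma_v = 1)
  m0 <- covariate_model("ktrans", theta_q = 3.3e-3, theta_sigma = 0)
  expect_equal(apply_covariates(m0, 0.02, 0, base)$sigma_v, 1)

  # sigma_v stays in (0, 1] over a wide covariate sweep
  for (k in 10^seq(-5, 0, by = 0.5)) {
    s <- apply_covariates(m, k, 0, base)$sigma_v
    expect_true(s > 0 && s <= 1)
  }

  # zero predictor makes Q_TU = 0: the subject cannot be predicted
  expect_error(apply_covariates(m, 0, 0, base), "unpredictable")

  # two-covariate structure: additive linear predictor in both equations
  m2 <- covariate_model("ktrans_vp", theta_q = c(2e-3, 1e-3),
                        theta_sigma = c(6, 3))
  p2 <- apply_covariates(m2, ktrans = 0.01, vp = 0.04, base)
  expect_equal(p2$q_tu, 2e-3 * 0.01 + 1e-3 * 0.04)
  expect_equal(p2$sigma_v, 1 / (1 + 6 * 0.01 + 3 * 0.04))
  # a Vp = 0 subject is retained, the predictor just loses the Vp term
  expect_equal(apply_covariates(m2, 0.01, 0, base)$q_tu, 2e-5)

  expect_error(covariate_model("ktrans", theta_q = 1), "length")
  expect_error(covariate_model("ktrans", theta_q = -1, theta_sigma = 1),
               "non-negative")
  expect_error(covariate_model("ktrans", theta_q = 0, theta_sigma = 1), "zero")
})

test_that("higher Ktrans means more permeable, better perfused, higher simulated uptake", {
  truth <- true_covariate_model()
  base <- tumor_params()
  ks <- c(1e-3, 5e-3, 0.02, 0.05)
  conc24 <- vapply(ks, function(k) {
    pars <- apply_covariates(truth, k, 0.02, base)
    dcepbpk:::tumor_conc_at(pars, plasma_pk(), 24 * 60)
  }, numeric(1))
  sigmas <- vapply(ks, function(k) apply_covariates(truth, k, 0.02, base)$sigma_v,
                   numeric(1))
  expect_true(all(diff(conc24) > 0))
  expect_true(all(diff(sigmas) < 0))
})

test_that("the base structure evaluates the likelihood once without optimization", {
  coh <- generate_cohort(small_groups(), seed = 5, noise = noise_model(obs_cv = 0.2))
  fit <- fit_population(coh, "base", tumor_params(), plasma_pk())
  expect_equal(fit$n_params, 1)                 # residual error only
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  expect_equal(nrow(fit$predictions), nrow(coh))
  expect_equal(fit$model$structure, "base")
  expect_true(all(fit$predictions$predicted > 0))
})

test_that("slopes are recovered from a noise-free cohort", {
  truth <- true_covariate_model()
  coh <- generate_cohort(small_groups(), truth, seed = 8,
                         noise = noise_model(obs_cv = 0))
  fit <- suppressWarnings(
    fit_population(coh, "ktrans", tumor_params(), plasma_pk(), quick_settings())
  )
  expect_equal(fit$model$theta_q[1], truth$theta_q[1], tolerance = 0.01)
  expect_equal(fit$model$theta_sigma[1], truth$theta_sigma[1], tolerance = 0.01)
  expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
})

test_that("fit_population validates its cohort", {
  coh <- generate_cohort(small_groups(), seed = 5)
  bad <- dplyr::mutate(coh, egfr_conc = 1e-8)
  expect_error(fit_population(bad, "ktrans", tumor_params(), plasma_pk()),
               "non-binding")
  miss <- dplyr::mutate(coh, ktrans = NA_real_)
  expect_error(fit_population(miss, "ktrans", tumor_params(), plasma_pk()),
               "missing Patlak")
})

test_that("a priori prediction reduces to the training model without target and is monotone in Ktrans", {
  truth <- true_covariate_model()
  base <- tumor_params()

  # without EGFR the binding-arm prediction is the non-binding model
  sim_nb <- predict_individual(truth, 0.02, 0.03, base, plasma_pk(),
                               t_grid = c(0, 1440))
  pars <- apply_covariates(truth, 0.02, 0.03, base)
  sim_ref <- simulate_tumor_pbpk(pars, plasma_pk(), t_grid = c(0, 1440))
  expect_identical(sim_nb$trajectory$tumor_total_conc,
                   sim_ref$trajectory$tumor_total_conc)

  # binding-arm predictions for subjects identical in all but Ktrans are ordered
  base_b <- tumor_params(c_egfr = 1.14e-7)
  p_lo <- predict_individual(truth, 0.003, 0.02, base_b, plasma_pk(),
                             t_grid = c(0, 4320))
  p_hi <- predict_individual(truth, 0.03, 0.02, base_b, plasma_pk(),
                             t_grid = c(0, 4320))
  expect_gt(dplyr::last(p_hi$trajectory$tumor_total_conc),
            dplyr::last(p_lo$trajectory$tumor_total_conc))

  # predict_cohort uses each subject's own MRI values and EGFR
  tb <- generate_cohort(small_groups(), truth, base, plasma_pk(),
                        noise_model(obs_cv = 0), seed = 3,
                        antibody = "target-binding")
  pred <- predict_cohort(truth, tb, base, plasma_pk())
  expect_equal(nrow(pred), nrow(tb))
  expect_equal(pred$predicted, tb$true_tumor_conc, tolerance = 1e-6)
})
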