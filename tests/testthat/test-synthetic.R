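test_that("cohort generation preserves counts, is deterministic, and is exact at zero noise", {
  groups <- group_phenotypes("non-binding")
  expect_equal(sum(groups$n_subjects), 26L)

  coh1 <- generate_cohort(groups, seed = 42, noise = noise_model(obs_cv = 0))
  coh2 <- generate_cohort(groups, seed = 42, noise = noise_model(obs_cv = 0))
  expect_identical(coh1, coh2)
  expect_equal(nrow(coh1), 26L)
  expect_equal(anyDuplicated(coh1$subject_id), 0L)

  # zero observation noise: the observation IS the simulator output
  expect_identical(coh1$observed_tumor_conc, coh1$true_tumor_conc)
  i <- 7L
  pars <- apply_covariates(true_covariate_model(), coh1$ktrans[i], coh1$vp[i],
                           tumor_params())
  sim <- simulate_tumor_pbpk(pars, plasma_pk(),
                             t_grid = c(0, coh1$terminal_time[i] * 60))
  expect_equal(coh1$observed_tumor_conc[i],
               dplyr::last(sim$trajectory$tumor_total_conc), tolerance = 1e-12)

  # terminal times are spread round-robin within each group
  panc <- dplyr::filter(coh1, group == "Panc-1")
  expect_equal(sort(panc$terminal_time), c(3, 8, 24, 72))

  expect_error(generate_cohort(groups[0, ], seed = 1), "empty")
  expect_error(
    generate_cohort(groups, truth = covariate_model("ktrans", theta_q = 0,
                                                    theta_sigma = 1), seed = 1),
    "zero"
  )
})

test_that("generated Ktrans spans at least 10-fold between extreme groups", {
  coh <- generate_cohort(group_phenotypes("non-binding"), seed = 3,
                         noise = noise_model())
  gm <- coh |>
    dplyr::group_by(group) |>
    dplyr::summarise(gm = exp(mean(log(ktrans))))
  expect_gte(max(gm$gm) / min(gm$gm), 10)
})

test_that("synthetic AIF respects the injection delay, the frame grid, and jitter settings", {
  p <- acq_protocol()
  aif <- clean_aif(p)
  expect_equal(nrow(aif), 70L)
  # 70 frames at 17 s cover 19.8 min of scanning
  expect_equal(70 * 17 / 60, 19.83, tolerance = 1e-3)
  expect_equal(max(aif$time_min), 69 * 17 / 60)
  expect_true(all(aif$cp_mm[aif$time_min < p$injection_time] == 0))
  expect_true(all(aif$cp_mm[aif$time_min >= p$injection_time] > 0))

  # zero jitter: different subjects and seeds give the same AIF values
  a1 <- generate_aif("a", p, noise_model(aif_variability = 0), seed = 1)
  a2 <- generate_aif("b", p, noise_model(aif_variability = 0), seed = 99)
  expect_equal(a1$cp_mm, a2$cp_mm)

  # with jitter, subjects differ
  b1 <- generate_aif("a", p, noise_model(aif_variability = 0.2), seed = 1)
  b2 <- generate_aif("a", p, noise_model(aif_variability = 0.2), seed = 2)
  expect_false(isTRUE(all.equal(b1$cp_mm, b2$cp_mm)))
})

test_that("forward DCE generation is linear in Vp and round-trips through the fitting pipeline", {
  p <- acq_protocol()
  aif <- clean_aif(p)
  quiet <- noise_model(dce_signal_cv = 0)

  # no enhancement at Ktrans = Vp = 0
  sig0 <- generate_dce_observation(0, 0, aif, t10 = 2000, p, quiet, seed = 1)
  expect_equal(diff(range(sig0$signal)), 0)

  expect_error(generate_dce_observation(-0.01, 0, aif, 2000, p, quiet), "ktrans")
  expect_error(generate_dce_observation(0.01, 1.5, aif, 2000, p, quiet), "vp")

  # doubling Vp (Ktrans = 0) doubles the concentration change at every frame
  s1 <- generate_dce_observation(0, 0.04, aif, 2000, p, quiet, seed = 1)
  s2 <- generate_dce_observation(0, 0.08, aif, 2000, p, quiet, seed = 1)
  c1 <- signal_to_concentration(s1, 2000, p)$conc_mm
  c2 <- signal_to_concentration(s2, 2000, p)$conc_mm
  expect_equal(c2, 2 * c1, tolerance = 1e-8)

  # noise-free forward/inverse consistency for several parameter pairs
  for (pars in list(c(0.01, 0.05), c(0.05, 0), c(0.002, 0.1))) {
    sig <- generate_dce_observation(pars[1], pars[2], aif, 2000, p, quiet, seed = 1)
    ct <- signal_to_concentration(sig, 2000, p)
    fit <- patlak_fit(ct, aif)
    expect_equal(fit$ktrans, pars[1], tolerance = 1e-6)
    expect_equal(fit$vp, pars[2], tolerance = 1e-6)
  }
})
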