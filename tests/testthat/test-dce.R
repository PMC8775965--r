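test_that("saturation-recovery T1 fitting recovers exact data and is scale invariant", {
  trs <- c(200, 400, 800, 1500, 3000, 5000)
  s <- 3.2 * (1 - exp(-trs / 2000))
  fit <- fit_t10(trs, s)
  expect_true(fit$converged)
  expect_equal(fit$t10, 2000, tolerance = 1e-6)
  expect_equal(fit$m0, 3.2, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # scaling the signals scales M0 and leaves T1 unchanged
  fit5 <- fit_t10(trs, 5 * s)
  expect_equal(fit5$t10, fit$t10, tolerance = 1e-8)
  expect_equal(fit5$m0, 5 * fit$m0, tolerance = 1e-8)

  # saturated (constant) signals drive T1 to the boundary and are flagged
  expect_warning(fitc <- fit_t10(trs, rep(1, 6)), "degenerate")
  expect_false(fitc$converged)

  expect_error(fit_t10(c(200, 200, 200), c(1, 1, 1)), "distinct")
  expect_error(fit_t10(trs, -s), "non-negative")
})

test_that("SPGR signal-to-concentration inversion is exact, monotone, and flags invalid frames", {
  p <- acq_protocol()
  t <- frame_times(p)
  conc <- c(rep(0, n_baseline_frames(p)),
            seq(0, 1.5, length.out = p$n_frames - n_baseline_frames(p)))
  sig <- tibble::tibble(time_min = t,
                        signal = concentration_to_signal(conc, 2000, 1000, p))

  out <- signal_to_concentration(sig, 2000, p)
  expect_false(any(out$excluded))
  expect_equal(out$conc_mm, conc, tolerance = 1e-9)

  # flat signal at baseline level implies zero concentration everywhere
  flat <- tibble::tibble(time_min = t, signal = rep(sig$signal[1], length(t)))
  expect_equal(signal_to_concentration(flat, 2000, p)$conc_mm,
               rep(0, length(t)), tolerance = 1e-10)

  # concentration is strictly increasing in post-baseline signal
  bumped <- sig
  bumped$signal[40] <- bumped$signal[40] * 1.01
  out2 <- signal_to_concentration(bumped, 2000, p)
  expect_gt(out2$conc_mm[40], out$conc_mm[40])
  expect_equal(out2$conc_mm[-40], out$conc_mm[-40])

  # signal above the SPGR saturation ceiling cannot be inverted -> flagged
  sat <- sig
  sat$signal[50] <- 1000 * sin(p$flip_angle * pi / 180) * 1.01
  out3 <- signal_to_concentration(sat, 2000, p)
  expect_true(out3$excluded[50])
  expect_false(any(out3$excluded[-50]))

  zero <- tibble::tibble(time_min = t, signal = rep(0, length(t)))
  expect_error(signal_to_concentration(zero, 2000, p), "baseline")
})

test_that("Patlak fitting is exact on noise-free data and matches the normal-equations oracle", {
  p <- acq_protocol()
  aif <- clean_aif(p)
  k_true <- 0.01
  vp_true <- 0.05
  ct <- tibble::tibble(
    time_min = aif$time_min,
    conc_mm = k_true * cumtrapz(aif$time_min, aif$cp_mm) + vp_true * aif$cp_mm
  )
  fit <- patlak_fit(ct, aif)
  expect_equal(fit$ktrans, k_true, tolerance = 1e-6)
  expect_equal(fit$vp, vp_true, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
  expect_identical(fit$active_constraints, "none")

  # independent unconstrained oracle: lm() on the two regressors
  noisy <- ct
  noisy$conc_mm <- withr::with_seed(1, ct$conc_mm + rnorm(nrow(ct), sd = 0.002))
  x1 <- cumtrapz(aif$time_min, aif$cp_mm)
  x2 <- aif$cp_mm
  ols <- stats::coef(stats::lm(noisy$conc_mm ~ 0 + x1 + x2))
  fit2 <- patlak_fit(noisy, aif)
  expect_identical(fit2$active_constraints, "none")
  expect_equal(fit2$ktrans, unname(ols[1]), tolerance = 1e-8)
  expect_equal(fit2$vp, unname(ols[2]), tolerance = 1e-8)
})

test_that("Patlak edge cases: null curves, pure-plasma signal, constraints, errors", {
  p <- acq_protocol()
  aif <- clean_aif(p)

  null_ct <- tibble::tibble(time_min = aif$time_min, conc_mm = 0)
  fit0 <- patlak_fit(null_ct, aif)
  expect_equal(c(fit0$ktrans, fit0$vp, fit0$rss), c(0, 0, 0))

  # constant Cp after injection with ct = Vp * Cp: pure plasma signal
  cp_const <- tibble::tibble(time_min = aif$time_min,
                             cp_mm = ifelse(aif$time_min < p$injection_time, 0, 2))
  ct_pp <- tibble::tibble(time_min = aif$time_min, conc_mm = 0.07 * cp_const$cp_mm)
  fit_pp <- patlak_fit(ct_pp, cp_const, fit_window = c(p$injection_time, Inf))
  expect_equal(fit_pp$ktrans, 0, tolerance = 1e-10)
  expect_equal(fit_pp$vp, 0.07, tolerance = 1e-10)

  # a decreasing curve would need Ktrans < 0; the constrained fit pins it at 0
  ct_neg <- tibble::tibble(time_min = aif$time_min,
                           conc_mm = -0.01 * cumtrapz(aif$time_min, aif$cp_mm))
  fit_neg <- patlak_fit(ct_neg, aif)
  expect_gte(fit_neg$ktrans, 0)
  expect_true(fit_neg$vp >= 0 && fit_neg$vp <= 1)

  zero_aif <- tibble::tibble(time_min = aif$time_min, cp_mm = 0)
  expect_error(patlak_fit(null_ct, zero_aif), "unidentifiable")
  expect_error(patlak_fit(null_ct[1:2, ], aif[1:2, ]), "3")
  expect_error(patlak_fit(null_ct, dplyr::mutate(aif, time_min = time_min + 0.5)),
               "time grid")
})

test_that("fit_dce runs the per-subject pipeline with each subject's own AIF", {
  p <- acq_protocol()
  noise <- noise_model(dce_signal_cv = 0, aif_variability = 0.2)
  subjects <- tibble::tibble(subject_id = c("m1", "m2"),
                             ktrans = c(0.02, 0.004), vp = c(0.05, 0.01))
  aifs <- purrr::map_dfr(1:2, ~ generate_aif(subjects$subject_id[.x], p, noise,
                                             seed = 100 + .x))
  signals <- purrr::map_dfr(1:2, function(i) {
    a <- dplyr::filter(aifs, subject_id == subjects$subject_id[i])
    dplyr::mutate(generate_dce_observation(subjects$ktrans[i], subjects$vp[i],
                                           a, 2000, p, noise, seed = i),
                  subject_id = subjects$subject_id[i], .before = 1)
  })
  t10s <- tibble::tibble(subject_id = subjects$subject_id, t10 = 2000)
  fits <- fit_dce(signals, aifs, t10s, p)
  expect_equal(fits$subject_id, subjects$subject_id)
  expect_equal(fits$ktrans, subjects$ktrans, tolerance = 1e-5)
  expect_equal(fits$vp, subjects$vp, tolerance = 1e-5)
})
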