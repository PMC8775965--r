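#' Arterial input function shape
#'
#' Bolus biexponential used by the synthetic AIF generator:
#' `Cp(t) = A1 exp(-l1 (t - t0)) + A2 exp(-l2 (t - t0))` for `t >= t0` (the
#' injection time) and 0 before. Defaults give a ~5 mM peak decaying over the
#' scan, a plausible murine gadobutrol profile. Measured, tabulated AIFs can
#' be used everywhere downstream; this form exists only to generate data.
#'
#' @param a1,a2 Amplitudes (mM).
#' @param lambda1,lambda2 Decay rates (1/min).
#' @return A list of class `aif_shape`.
#' @export
aif_shape <- function(a1 = 4, lambda1 = 0.25, a2 = 1, lambda2 = 0.02) {
  stopifnot(a1 >= 0, a2 >= 0, lambda1 > 0, lambda2 > 0)
  structure(list(a1 = a1, lambda1 = lambda1, a2 = a2, lambda2 = lambda2),
            class = "aif_shape")
}

#' Generate a synthetic per-subject arterial input function
#'
#' Samples the bolus-biexponential AIF on the protocol's frame grid, with
#' per-subject multiplicative lognormal jitter on the amplitudes and decay
#' rates controlled by `noise$aif_variability`. `Cp = 0` strictly before the
#' injection time.
#'
#' @param subject_id Identifier copied into the output.
#' @param protocol An [acq_protocol()].
#' @param noise A [noise_model()].
#' @param seed Integer seed (the jitter is a deterministic function of it).
#' @param shape An [aif_shape()].
#' @return Tibble: `subject_id`, `time_min`, `cp_mm`.
#' @export
generate_aif <- function(subject_id, protocol, noise = noise_model(), seed = 1,
                         shape = aif_shape()) {
  stopifnot(inherits(protocol, "acq_protocol"), inherits(noise, "noise_model"))
  jit <- withr::with_seed(seed, lognormal_factor(4, noise$aif_variability))
  t <- frame_times(protocol)
  tau <- t - protocol$injection_time
  cp <- ifelse(tau < 0, 0,
               shape$a1 * jit[1] * exp(-shape$lambda1 * jit[2] * tau) +
               shape$a2 * jit[3] * exp(-shape$lambda2 * jit[4] * tau))
  tibble::tibble(subject_id = subject_id, time_min = t, cp_mm = cp)
}

#' Forward-simulate a DCE signal curve from Patlak parameters
#'
#' Generates the tumor concentration curve from the forward Patlak model
#' (`Ct = Ktrans * int Cp + Vp * Cp` on the AIF's frame grid), converts it to
#' SPGR signal with [concentration_to_signal()], and applies proportional
#' signal noise. With zero noise the curve round-trips exactly through
#' [signal_to_concentration()] + [patlak_fit()].
#'
#' @param true_ktrans,true_vp Generating Patlak parameters (>= 0).
#' @param aif AIF tibble (`time_min`, `cp_mm`), e.g. from [generate_aif()].
#' @param t10 Pre-contrast T1 (ms).
#' @param protocol An [acq_protocol()].
#' @param noise A [noise_model()] (`dce_signal_cv` is used).
#' @param seed Integer seed for the noise draw.
#' @param m0 Signal scale.
#' @return Tibble: `time_min`, `signal`.
#' @export
generate_dce_observation <- function(true_ktrans, true_vp, aif, t10, protocol,
                                     noise = noise_model(), seed = 1, m0 = 1000) {
  check_number(true_ktrans, "true_ktrans", lower = 0)
  check_number(true_vp, "true_vp", lower = 0, upper = 1)
  check_number(t10, "t10", lower = 1e-6)
  ct <- true_ktrans * cumtrapz(aif$time_min, aif$cp_mm) + true_vp * aif$cp_mm
  sig <- concentration_to_signal(ct, t10, m0, protocol)
  fac <- withr::with_seed(seed, lognormal_factor(length(sig), noise$dce_signal_cv))
  tibble::tibble(time_min = aif$time_min, signal = sig * fac)
}

#' Generate synthetic saturation-recovery signals
#'
#' @param t10 True T1 (ms).
#' @param m0 Signal scale.
#' @param protocol An [acq_protocol()] (supplies the recovery times).
#' @param noise A [noise_model()] (`dce_signal_cv` reused as the SR signal CV).
#' @param seed Integer seed.
#' @return Tibble: `recovery_time`, `signal`.
#' @export
generate_sr_signals <- function(t10, m0 = 1000, protocol = acq_protocol(),
                                noise = noise_model(), seed = 1) {
  tr <- protocol$sr_recovery_times
  s <- m0 * (1 - exp(-tr / t10))
  fac <- withr::with_seed(seed, lognormal_factor(length(s), noise$dce_signal_cv))
  tibble::tibble(recovery_time = tr, signal = s * fac)
}

#' The default ground-truth covariate model of the generator
#'
#' A Ktrans structure with slopes chosen so that a typical well-perfused
#' xenograft (Ktrans = 0.03/min) maps onto the base parameter values
#' (`Q_TU = 1e-4` L/min, `sigma_v ~ 0.73`).
#'
#' @return A [covariate_model()].
#' @export
true_covariate_model <- function() {
  covariate_model("ktrans", theta_q = 3.3e-3, theta_sigma = 12, error_cv = 0)
}

#' Generate a synthetic xenograft cohort
#'
#' Draws per-subject true MRI parameters from each group's distribution
#' (lognormal Ktrans; truncated-normal Vp with an optional point mass at 0),
#' allocates terminal sacrifice times round-robin across the study timepoints
#' within each group so even small groups cover early and late times, derives
#' subject-specific PBPK parameters through the ground-truth covariate model,
#' and produces one terminal tumor and plasma observation per subject from
#' the PBPK simulator with proportional (lognormal) observation error.
#'
#' @param groups Group phenotype tibble (see [group_phenotypes()]).
#' @param truth Ground-truth [covariate_model()] linking Ktrans/Vp to `Q_TU`
#'   and `sigma_v` (must have non-degenerate slopes).
#' @param base Base [tumor_params()].
#' @param plasma A [plasma_pk()].
#' @param noise A [noise_model()] (`obs_cv` is used).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @param antibody Arm label. For `"non-binding"` the group EGFR
#'   concentrations are forced to zero.
#' @param terminal_times Candidate terminal times (h).
#' @return A cohort tibble, one row per subject: `subject_id`, `group`,
#'   `antibody`, `dose`, `terminal_time` (h), true `ktrans`/`vp`,
#'   subject-level `q_tu_true`/`sigma_v_true`, `egfr_conc`,
#'   `true_tumor_conc` (noise-free simulator output, M),
#'   `observed_tumor_conc`, `observed_plasma_conc` (M).
#' @export
#' @examples
#' coh <- generate_cohort(group_phenotypes(), true_covariate_model(),
#'                        tumor_params(), plasma_pk(), noise_model(), seed = 7)
#' dplyr::count(coh, group)
generate_cohort <- function(groups, truth = true_covariate_model(),
                            base = tumor_params(), plasma = plasma_pk(),
                            noise = noise_model(), seed = 1,
                            antibody = c("non-binding", "target-binding"),
                            terminal_times = c(3, 8, 24, 72, 144)) {
  stopifnot(is.data.frame(groups), inherits(truth, "covariate_model"),
            inherits(base, "tumor_params"), inherits(plasma, "plasma_pk"),
            inherits(noise, "noise_model"))
  antibody <- match.arg(antibody)
  if (nrow(groups) == 0) abort("empty group list")
  if (truth$structure %in% c("ktrans", "vp", "ktrans_vp") &&
      (all(truth$theta_q == 0) || all(truth$theta_sigma == 0))) {
    abort("non-invertible truth structure: all slopes zero")
  }

  withr::with_seed(seed, {
    rows <- purrr::pmap_dfr(groups, function(name, ktrans_logmean, ktrans_logsd,
                                             vp_mean, vp_sd, vp_zero_prob,
                                             egfr_conc, n_subjects, ...) {
      n <- n_subjects
      ktrans <- exp(rnorm(n, ktrans_logmean, ktrans_logsd))
      vp <- pmax(rnorm(n, vp_mean, vp_sd), 0)
      vp[runif(n) < vp_zero_prob] <- 0
      tibble::tibble(
        group = name,
        ktrans = ktrans, vp = vp,
        egfr_conc = if (antibody == "non-binding") 0 else egfr_conc,
        terminal_time = terminal_times[(seq_len(n) - 1) %% length(terminal_times) + 1]
      )
    })
    rows$subject_id <- sprintf("%s-%02d", substr(antibody, 1, 2), seq_len(nrow(rows)))
    rows$antibody <- antibody
    rows$dose <- plasma$dose

    pars <- purrr::pmap(list(rows$ktrans, rows$vp, rows$egfr_conc),
                        function(k, v, egfr) {
                          apply_covariates(truth, k, v,
                                           update_tumor_params(base, c_egfr = egfr))
                        })
    rows$q_tu_true <- purrr::map_dbl(pars, "q_tu")
    rows$sigma_v_true <- purrr::map_dbl(pars, "sigma_v")
    rows$true_tumor_conc <- purrr::map2_dbl(pars, rows$terminal_time,
                                            ~ tumor_conc_at(.x, plasma, .y * 60))
    n <- nrow(rows)
    rows$observed_tumor_conc <- rows$true_tumor_conc * lognormal_factor(n, noise$obs_cv)
    rows$observed_plasma_conc <- plasma_forcing(plasma, rows$terminal_time * 60) *
      lognormal_factor(n, noise$obs_cv)

    dplyr::select(rows, "subject_id", "group", "antibody", "dose",
                  "terminal_time", "ktrans", "vp", "egfr_conc",
                  "q_tu_true", "sigma_v_true", "true_tumor_conc",
                  "observed_tumor_conc", "observed_plasma_conc")
  })
}

#' Generate DCE-MRI curves for every subject of a cohort
#'
#' Produces, per subject: a jittered AIF, a noisy tumor SPGR signal curve from
#' the subject's true Patlak parameters, and saturation-recovery signals for
#' T1 mapping. Seeds are derived deterministically from `seed` and the row
#' index.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param protocol An [acq_protocol()].
#' @param noise A [noise_model()].
#' @param seed Integer base seed.
#' @param t10 True pre-contrast T1 (ms) shared across subjects.
#' @param m0 Signal scale.
#' @return A list of three long tibbles: `aifs` (`subject_id`, `time_min`,
#'   `cp_mm`), `signals` (`subject_id`, `time_min`, `signal`), and
#'   `sr_signals` (`subject_id`, `recovery_time`, `signal`).
#' @export
generate_dce_curves <- function(cohort, protocol = acq_protocol(),
                                noise = noise_model(), seed = 1,
                                t10 = 2000, m0 = 1000) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  res <- purrr::map(seq_len(n), function(i) {
    sid <- cohort$subject_id[i]
    aif <- generate_aif(sid, protocol, noise, seed = seed + 7L * i)
    sig <- generate_dce_observation(cohort$ktrans[i], cohort$vp[i], aif, t10,
                                    protocol, noise, seed = seed + 7L * i + 1L,
                                    m0 = m0)
    sr <- generate_sr_signals(t10, m0, protocol, noise, seed = seed + 7L * i + 2L)
    list(aif = aif,
         sig = dplyr::mutate(sig, subject_id = sid, .before = 1),
         sr = dplyr::mutate(sr, subject_id = sid, .before = 1))
  })
  list(aifs = purrr::map_dfr(res, "aif"),
       signals = purrr::map_dfr(res, "sig"),
       sr_signals = purrr::map_dfr(res, "sr"))
}
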