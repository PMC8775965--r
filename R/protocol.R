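#' DCE-MRI acquisition protocol
#'
#' Bundles the acquisition settings needed to simulate and invert spoiled
#' gradient-echo (SPGR) DCE-MRI signal: the dynamic frame grid, the contrast
#' injection time, the SPGR sequence parameters, the contrast agent relaxivity,
#' and the saturation-recovery times used for pre-contrast T1 mapping.
#'
#' @param frame_interval Dynamic frame spacing in seconds.
#' @param n_frames Number of dynamic frames (>= 3).
#' @param injection_time Contrast injection time in minutes after scan start.
#' @param TR SPGR repetition time in milliseconds.
#' @param flip_angle SPGR flip angle in degrees, in (0, 90).
#' @param r1_relaxivity Longitudinal relaxivity of the contrast agent in
#'   L mmol^-1 s^-1. The default (3.3) is a typical high-field value for
#'   gadobutrol and is an assumption of this package, not a measured input;
#'   set it to the value appropriate for your agent and field strength.
#' @param sr_recovery_times Saturation-recovery TR values (ms) for T1 mapping.
#'
#' @return An object of class `acq_protocol` (a list).
#' @export
#' @examples
#' p <- acq_protocol()
#' frame_times(p)[1:5]
acq_protocol <- function(frame_interval = 17,
                         n_frames = 70,
                         injection_time = 2,
                         TR = 10,
                         flip_angle = 20,
                         r1_relaxivity = 3.3,
                         sr_recovery_times = c(200, 400, 800, 1500, 3000, 5000)) {
  check_number(frame_interval, "frame_interval", lower = 1e-6)
  check_number(n_frames, "n_frames", lower = 3)
  check_number(injection_time, "injection_time", lower = 0)
  check_number(TR, "TR", lower = 1e-6)
  check_number(flip_angle, "flip_angle", lower = 1e-6, upper = 90 - 1e-6)
  check_number(r1_relaxivity, "r1_relaxivity", lower = 1e-6)
  stopifnot(length(sr_recovery_times) >= 3, all(sr_recovery_times > 0))
  if (injection_time * 60 >= frame_interval * n_frames) {
    abort("`injection_time` must fall within the scan duration")
  }
  structure(
    list(
      frame_interval = frame_interval, n_frames = as.integer(n_frames),
      injection_time = injection_time, TR = TR, flip_angle = flip_angle,
      r1_relaxivity = r1_relaxivity, sr_recovery_times = sr_recovery_times
    ),
    class = "acq_protocol"
  )
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("<acq_protocol>\n")
  cat(sprintf("  %d frames every %g s, injection at %g min\n",
              x$n_frames, x$frame_interval, x$injection_time))
  cat(sprintf("  SPGR TR = %g ms, flip = %g deg, r1 = %g L/mmol/s\n",
              x$TR, x$flip_angle, x$r1_relaxivity))
  invisible(x)
}

#' Dynamic frame times of a protocol
#'
#' @param protocol An [acq_protocol()].
#' @return Frame mid/start times in minutes from scan start (first frame at 0).
#' @export
frame_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) * protocol$frame_interval / 60
}

# number of pre-injection (baseline) frames implied by the protocol
n_baseline_frames <- function(protocol) {
  sum(frame_times(protocol) < protocol$injection_time)
}

#' Noise model for synthetic data generation
#'
#' All components are proportional (lognormal, unit median) with the stated
#' coefficient of variation.
#'
#' @param dce_signal_cv CV of multiplicative noise on the DCE signal.
#' @param obs_cv CV of the error on terminal tumor/plasma concentrations.
#' @param aif_variability CV of the per-subject jitter applied to the arterial
#'   input function amplitudes and decay rates.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(dce_signal_cv = 0.05, obs_cv = 0.2, aif_variability = 0.15) {
  check_number(dce_signal_cv, "dce_signal_cv", lower = 0)
  check_number(obs_cv, "obs_cv", lower = 0)
  check_number(aif_variability, "aif_variability", lower = 0)
  structure(
    list(dce_signal_cv = dce_signal_cv, obs_cv = obs_cv,
         aif_variability = aif_variability),
    class = "noise_model"
  )
}

#' Default xenograft group phenotypes
#'
#' One row per tumor model, giving the between-subject distributions of the
#' true DCE-MRI parameters, the EGFR expression used for a target-binding
#' antibody, and the arm sizes. The four default groups emulate xenograft
#' models with distinct vascular phenotypes: two well-perfused lines (LS174T,
#' NCI-N87), an anti-angiogenic-treated line with ~10-fold lower Ktrans
#' (LS174T+sorafenib), and a poorly vascularized stroma-rich line (Panc-1)
#' where Vp is frequently zero. Group EGFR concentrations are cell-line
#' specific literature values; arm sizes follow the two study arms
#' (26 non-binding, 23 target-binding subjects).
#'
#' @param antibody `"non-binding"` or `"target-binding"`; selects the arm
#'   sizes and whether `egfr_conc` is zeroed (a non-binding antibody sees no
#'   target regardless of expression).
#' @return A tibble with columns `name`, `ktrans_logmean`, `ktrans_logsd`,
#'   `vp_mean`, `vp_sd`, `vp_zero_prob`, `egfr_conc` (M), `n_subjects`.
#' @export
#' @examples
#' group_phenotypes()
group_phenotypes <- function(antibody = c("non-binding", "target-binding")) {
  antibody <- match.arg(antibody)
  g <- tibble::tibble(
    name = c("LS174T", "LS174T+sorafenib", "NCI-N87", "Panc-1"),
    ktrans_logmean = log(c(0.03, 0.003, 0.025, 0.0025)),
    ktrans_logsd = c(0.4, 0.4, 0.4, 0.4),
    vp_mean = c(0.03, 0.01, 0.03, 0.005),
    vp_sd = c(0.02, 0.01, 0.02, 0.005),
    vp_zero_prob = c(0.2, 0.4, 0.2, 0.5),
    egfr_conc = c(3.53e-8, 3.53e-8, 1.14e-7, 9.24e-8),
    n_subjects = if (antibody == "non-binding") c(10L, 7L, 5L, 4L) else c(9L, 6L, 5L, 3L)
  )
  if (antibody == "non-binding") g$egfr_conc <- 0
  g
}
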