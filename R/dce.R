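#' Saturation-recovery T1 estimation
#'
#' Fits the saturation-recovery signal model `S(TR) = M0 * (1 - exp(-TR/T1))`
#' to pre-contrast signals acquired at multiple repetition times by profiled
#' least squares: for a candidate T1 the optimal M0 is available in closed
#' form, leaving a one-dimensional search over log T1.
#'
#' @param recovery_times Repetition times in ms (>= 3 distinct values).
#' @param signals Non-negative signal intensities, same length.
#' @return An object of class `t10_fit` with elements `t10` (ms), `m0`, `rss`,
#'   and `converged`. Degenerate data that drive T1 to the search boundary
#'   (e.g. fully saturated, constant signals) are flagged `converged = FALSE`
#'   with a warning rather than silently clipped.
#' @export
#' @examples
#' trs <- c(200, 400, 800, 1500, 3000, 5000)
#' fit_t10(trs, 1 - exp(-trs / 2000))
fit_t10 <- function(recovery_times, signals) {
  stopifnot(length(recovery_times) == length(signals))
  if (length(unique(recovery_times)) < 3) abort("need >= 3 distinct recovery times")
  if (any(signals < 0)) abort("signals must be non-negative")
  tr <- as.numeric(recovery_times)
  s <- as.numeric(signals)

  bounds <- log(c(1e-2, 1e5))
  profile_rss <- function(log_t1) {
    g <- 1 - exp(-tr / exp(log_t1))
    m0 <- sum(s * g) / sum(g^2)
    sum((s - m0 * g)^2)
  }
  opt <- optimize(profile_rss, interval = bounds, tol = 1e-9)
  t10 <- exp(opt$minimum)
  g <- 1 - exp(-tr / t10)
  m0 <- sum(s * g) / sum(g^2)

  # T1 far outside the sampled recovery-time range is not identifiable:
  # constant (saturated) signals drive T1 -> 0, non-recovering signals
  # drive it beyond the search interval
  degenerate <- t10 < min(tr) / 5 || t10 > 20 * max(tr)
  if (degenerate) {
    warn("T1 estimate degenerate (outside the range resolvable by the recovery times); large uncertainty")
  }
  structure(
    list(t10 = t10, m0 = m0, rss = opt$objective, converged = !degenerate),
    class = "t10_fit"
  )
}

#' @export
print.t10_fit <- function(x, ...) {
  cat(sprintf("<t10_fit> T1 = %.1f ms, M0 = %.4g, rss = %.3g%s\n",
              x$t10, x$m0, x$rss, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# forward SPGR steady-state signal; r1_per_s in 1/s, TR in ms
spgr_signal <- function(r1_per_s, m0, TR_ms, flip_deg) {
  a <- flip_deg * pi / 180
  e1 <- exp(-TR_ms * r1_per_s / 1000)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Generate an SPGR signal curve from a concentration curve
#'
#' Forward model used by the synthetic-data generator and as the inversion
#' oracle for [signal_to_concentration()]: `R1(t) = 1/T10 + r1 * C(t)` with
#' linear relaxivity, then the spoiled-gradient-echo steady-state equation.
#'
#' @param conc_mm Contrast agent concentration (mM), vectorized.
#' @param t10 Pre-contrast T1 in ms.
#' @param m0 Equilibrium signal scale.
#' @param protocol An [acq_protocol()] supplying TR, flip angle, relaxivity.
#' @return Signal intensities.
#' @export
concentration_to_signal <- function(conc_mm, t10, m0, protocol) {
  stopifnot(inherits(protocol, "acq_protocol"), t10 > 0)
  r10 <- 1000 / t10                           # 1/s
  r1 <- r10 + protocol$r1_relaxivity * conc_mm
  spgr_signal(r1, m0, protocol$TR, protocol$flip_angle)
}

#' Convert a DCE signal curve to contrast-agent concentration
#'
#' Inverts the spoiled-gradient-echo steady-state equation
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR * R1)`, frame by
#' frame for `R1(t)`, calibrating `M0` from the mean pre-injection baseline
#' signal together with `R10 = 1/T10`, and maps relaxation rate to
#' concentration with linear relaxivity: `C(t) = (R1(t) - R10) / r1`.
#'
#' @param signal_curve Data frame with columns `time_min` and `signal`.
#' @param t10 Pre-contrast T1: a [fit_t10()] result or a number (ms).
#' @param protocol An [acq_protocol()].
#' @param baseline_frames Number of pre-injection frames averaged for the M0
#'   calibration; default derived from `injection_time` and `frame_interval`.
#' @return A tibble with `time_min`, `conc_mm`, and `excluded` (frames whose
#'   signal implies `E1` outside (0, 1) are flagged and get `NA`
#'   concentration; they are excluded from any downstream fit).
#' @export
signal_to_concentration <- function(signal_curve, t10, protocol,
                                    baseline_frames = NULL) {
  stopifnot(is.data.frame(signal_curve),
            all(c("time_min", "signal") %in% names(signal_curve)),
            inherits(protocol, "acq_protocol"))
  t10_ms <- if (inherits(t10, "t10_fit")) t10$t10 else t10
  check_number(t10_ms, "t10", lower = 1e-6)
  baseline_frames <- baseline_frames %||% n_baseline_frames(protocol)
  if (baseline_frames < 1) abort("need at least one pre-injection baseline frame")

  a <- protocol$flip_angle * pi / 180
  s <- signal_curve$signal
  s_base <- mean(s[seq_len(baseline_frames)])
  if (!is.finite(s_base) || s_base <= 0) abort("baseline signal is zero or invalid")

  r10 <- 1000 / t10_ms                        # 1/s
  e10 <- exp(-protocol$TR * r10 / 1000)
  f10 <- (1 - e10) / (1 - e10 * cos(a))
  m0 <- s_base / (sin(a) * f10)               # baseline-calibrated signal scale

  sn <- s / (m0 * sin(a))
  e1 <- (1 - sn) / (1 - sn * cos(a))
  valid <- is.finite(e1) & e1 > 0 & e1 < 1
  r1 <- rep(NA_real_, length(e1))
  r1[valid] <- -log(e1[valid]) * 1000 / protocol$TR
  conc <- (r1 - r10) / protocol$r1_relaxivity

  tibble::tibble(time_min = signal_curve$time_min, conc_mm = conc,
                 excluded = !valid)
}

#' Fit the Patlak model to a tumor concentration curve
#'
#' The Patlak model assumes no reflux of contrast agent from the interstitium
#' back to plasma: `Ct(t) = Ktrans * int_0^t Cp dtau + Vp * Cp(t)`. Because the
#' model is linear in (Ktrans, Vp), the constrained least-squares problem
#' (`Ktrans >= 0`, `0 <= Vp <= 1`) is solved exactly by enumerating the
#' Karush-Kuhn-Tucker candidates of the two-parameter normal equations; no
#' iterative optimizer or starting values are involved. The plasma integral is
#' computed by the trapezoid rule on the frame grid of the AIF, always from
#' time zero, regardless of the fit window.
#'
#' @param ct Tumor concentration curve: data frame with `time_min`, `conc_mm`,
#'   and optionally `excluded` (flagged frames are dropped from the fit).
#' @param aif Arterial input function: data frame with `time_min` and `cp_mm`
#'   on the same time grid as `ct`.
#' @param fit_window Optional `c(tmin, tmax)` in minutes restricting the
#'   frames entering the objective (default: all frames).
#' @return An object of class `patlak_fit`: `ktrans` (1/min), `vp`, `rss`,
#'   `n_points`, `converged`, and `active_constraints` (character).
#' @export
#' @examples
#' t <- seq(0, 19, by = 0.25)
#' aif <- tibble::tibble(time_min = t, cp_mm = ifelse(t < 2, 0, 4 * exp(-0.1 * (t - 2))))
#' ct <- tibble::tibble(time_min = t,
#'                      conc_mm = 0.01 * cumtrapz(t, aif$cp_mm) + 0.05 * aif$cp_mm)
#' patlak_fit(ct, aif)
patlak_fit <- function(ct, aif, fit_window = NULL) {
  stopifnot(is.data.frame(ct), is.data.frame(aif),
            all(c("time_min", "conc_mm") %in% names(ct)),
            all(c("time_min", "cp_mm") %in% names(aif)))
  if (nrow(ct) != nrow(aif) ||
      max(abs(ct$time_min - aif$time_min)) > 1e-8 * max(1, max(aif$time_min))) {
    abort("tumor curve and AIF must share the same time grid")
  }
  if (is.unsorted(aif$time_min, strictly = TRUE)) abort("times must be strictly increasing")
  if (nrow(ct) < 3) abort("fewer than 3 usable frames")
  if (any(aif$cp_mm < 0)) abort("AIF must be non-negative")
  if (all(aif$cp_mm == 0)) abort("all-zero AIF: Patlak parameters are unidentifiable")

  int_cp <- cumtrapz(aif$time_min, aif$cp_mm)
  use <- is.finite(ct$conc_mm)
  if ("excluded" %in% names(ct)) use <- use & !ct$excluded
  if (!is.null(fit_window)) {
    use <- use & ct$time_min >= fit_window[1] & ct$time_min <= fit_window[2]
  }
  if (sum(use) < 3) abort("fewer than 3 usable frames")

  x1 <- int_cp[use]; x2 <- aif$cp_mm[use]; y <- ct$conc_mm[use]
  rss_of <- function(k, v) sum((y - k * x1 - v * x2)^2)

  cand <- list()
  xtx <- rbind(c(sum(x1^2), sum(x1 * x2)), c(sum(x1 * x2), sum(x2^2)))
  xty <- c(sum(x1 * y), sum(x2 * y))
  det_xtx <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2]^2
  if (det_xtx > 1e-12 * xtx[1, 1] * xtx[2, 2]) {
    b <- solve(xtx, xty)
    if (b[1] >= 0 && b[2] >= 0 && b[2] <= 1) {
      cand <- c(cand, list(c(b[1], b[2], "none")))
    }
  }
  if (sum(x2^2) > 0) {                        # Ktrans pinned at 0
    v <- min(max(sum(x2 * y) / sum(x2^2), 0), 1)
    cand <- c(cand, list(c(0, v, "ktrans=0")))
  }
  if (sum(x1^2) > 0) {                        # Vp pinned at 0 or 1
    cand <- c(cand, list(c(max(sum(x1 * y) / sum(x1^2), 0), 0, "vp=0")))
    cand <- c(cand, list(c(max(sum(x1 * (y - x2)) / sum(x1^2), 0), 1, "vp=1")))
  }
  cand <- c(cand, list(c(0, 0, "ktrans=0,vp=0"), c(0, 1, "ktrans=0,vp=1")))

  rss <- vapply(cand, function(cc) rss_of(as.numeric(cc[1]), as.numeric(cc[2])), 0)
  best <- cand[[which.min(rss)]]
  structure(
    list(ktrans = as.numeric(best[1]), vp = as.numeric(best[2]),
         rss = min(rss), n_points = sum(use), converged = TRUE,
         active_constraints = best[3]),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Ktrans = %.4g /min, Vp = %.4g (rss = %.3g, n = %d%s)\n",
              x$ktrans, x$vp, x$rss, x$n_points,
              if (x$active_constraints == "none") "" else paste0(", at ", x$active_constraints)))
  invisible(x)
}

#' Fit DCE kinetics for every subject of a cohort
#'
#' Runs the per-subject pipeline [signal_to_concentration()] then
#' [patlak_fit()] over long-format curve tables, using each subject's own AIF.
#'
#' @param signals Long tibble of tumor signal curves: `subject_id`,
#'   `time_min`, `signal`.
#' @param aifs Long tibble of AIFs: `subject_id`, `time_min`, `cp_mm`.
#' @param t10s Tibble with `subject_id` and `t10` (ms).
#' @param protocol An [acq_protocol()].
#' @param fit_window Optional window passed to [patlak_fit()]; default is all
#'   post-injection frames.
#' @return A tibble, one row per subject: `subject_id`, `ktrans`, `vp`, `rss`,
#'   `n_points`, `converged`, `active_constraints`.
#' @export
fit_dce <- function(signals, aifs, t10s, protocol,
                    fit_window = c(protocol$injection_time, Inf)) {
  stopifnot(all(c("subject_id", "time_min", "signal") %in% names(signals)),
            all(c("subject_id", "time_min", "cp_mm") %in% names(aifs)),
            all(c("subject_id", "t10") %in% names(t10s)))
  ids <- unique(signals$subject_id)
  purrr::map_dfr(ids, function(id) {
    sig <- dplyr::filter(signals, .data$subject_id == id)
    aif <- dplyr::filter(aifs, .data$subject_id == id)
    t10 <- t10s$t10[match(id, t10s$subject_id)]
    ct <- signal_to_concentration(sig, t10, protocol)
    fit <- patlak_fit(ct, aif, fit_window = fit_window)
    n_excl <- sum(ct$excluded)
    if (n_excl > 0) {
      warn(sprintf("subject %s: %d frame(s) excluded (non-invertible signal)", id, n_excl))
    }
    tibble::tibble(subject_id = id, ktrans = fit$ktrans, vp = fit$vp,
                   rss = fit$rss, n_points = fit$n_points,
                   converged = fit$converged,
                   active_constraints = fit$active_constraints)
  })
}
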