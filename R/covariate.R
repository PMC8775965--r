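#' Covariate model linking DCE-MRI parameters to PBPK parameters
#'
#' Encodes the candidate structures relating the MRI parameters Ktrans and Vp
#' to the tumor PBPK parameters for plasma flow (`Q_TU`) and the vascular
#' reflection coefficient (`sigma_v`):
#'
#' * `Q_TU = theta_q . x` (slope through the origin), and
#' * `sigma_v = 1 / (1 + theta_sigma . x)`, a form that cannot exceed 1,
#'
#' where `x` is Ktrans, Vp, or for the two-covariate structure the additive
#' linear predictor `theta_1 * Ktrans + theta_2 * Vp` inside both equations.
#' The `base` structure applies no covariates (fixed base parameters); the
#' `population` structure carries directly fitted shared values of `Q_TU` and
#' `sigma_v` without covariates.
#'
#' @param structure One of `"base"`, `"population"`, `"ktrans"`, `"vp"`,
#'   `"ktrans_vp"`.
#' @param theta_q Non-negative slope vector for `Q_TU` (length 0, 0, 1, 1, 2
#'   by structure). Units: L (slope on a 1/min covariate yields L/min).
#' @param theta_sigma Non-negative slope vector for `sigma_v` (units: min).
#' @param error_cv Proportional residual error (CV) of the observation model.
#' @param q_tu,sigma_v Shared fixed effects, only for `structure = "population"`.
#' @return An object of class `covariate_model`.
#' @export
#' @examples
#' covariate_model("ktrans", theta_q = 3.3e-3, theta_sigma = 12)
covariate_model <- function(structure = c("base", "population", "ktrans", "vp", "ktrans_vp"),
                            theta_q = numeric(), theta_sigma = numeric(),
                            error_cv = 0.2, q_tu = NULL, sigma_v = NULL) {
  structure <- match.arg(structure)
  len <- c(base = 0L, population = 0L, ktrans = 1L, vp = 1L, ktrans_vp = 2L)[[structure]]
  if (length(theta_q) != len || length(theta_sigma) != len) {
    abort(sprintf("structure '%s' requires slope vectors of length %d", structure, len))
  }
  if (any(theta_q < 0) || any(theta_sigma < 0)) {
    abort("slopes must be non-negative (Q_TU and the sigma denominator must stay positive)")
  }
  # theta_sigma may be all zero (sigma_v -> 1, fully reflective); theta_q may
  # not, since Q_TU = theta . x must stay positive for any positive covariate
  if (len > 0 && all(theta_q == 0)) {
    abort("degenerate covariate model: Q_TU slopes are all zero")
  }
  if (structure == "population") {
    check_number(q_tu %||% NA_real_, "q_tu", lower = 1e-12)
    check_number(sigma_v %||% NA_real_, "sigma_v", lower = 0, upper = 1)
  }
  base::structure(
    list(structure = structure, theta_q = theta_q, theta_sigma = theta_sigma,
         error_cv = error_cv, q_tu = q_tu, sigma_v = sigma_v),
    class = "covariate_model"
  )
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("<covariate_model>", x$structure, "\n")
  if (length(x$theta_q)) {
    cat("  theta_q     =", paste(signif(x$theta_q, 4), collapse = ", "), "L\n")
    cat("  theta_sigma =", paste(signif(x$theta_sigma, 4), collapse = ", "), "min\n")
  }
  if (x$structure == "population") {
    cat(sprintf("  Q_TU = %.4g L/min, sigma_v = %.4g\n", x$q_tu, x$sigma_v))
  }
  invisible(x)
}

# linear predictors given a model and MRI parameters
covariate_predictor <- function(model, ktrans, vp) {
  x <- switch(model$structure,
    ktrans = cbind(ktrans),
    vp = cbind(vp),
    ktrans_vp = cbind(ktrans, vp),
    abort("no covariate predictor for this structure")
  )
  list(q = drop(x %*% model$theta_q), sigma = drop(x %*% model$theta_sigma))
}

#' Apply a covariate model to obtain subject-specific PBPK parameters
#'
#' Maps a subject's MRI parameters onto `Q_TU` and `sigma_v` according to the
#' covariate structure, leaving all other parameters at their base values. The
#' returned `sigma_v` always lies in (0, 1] by construction.
#'
#' @param model A [covariate_model()].
#' @param ktrans Subject Ktrans (1/min, >= 0).
#' @param vp Subject Vp (>= 0).
#' @param base A [tumor_params()] supplying all non-covariate parameters
#'   (including the group's `c_egfr`).
#' @return A [tumor_params()] object for the subject.
#' @export
#' @examples
#' m <- covariate_model("ktrans", theta_q = 3.3e-3, theta_sigma = 12)
#' apply_covariates(m, ktrans = 0.03, vp = 0.02, base = tumor_params())
apply_covariates <- function(model, ktrans, vp, base) {
  stopifnot(inherits(model, "covariate_model"), inherits(base, "tumor_params"))
  check_number(ktrans, "ktrans", lower = 0)
  check_number(vp, "vp", lower = 0)
  # lymph is filtrate of the tumor plasma flow, so when Q_TU is rescaled the
  # lymph flow keeps the base lymph:plasma flow ratio (L stays below Q even
  # for poorly perfused tumors)
  lymph_ratio <- base$l_tu / base$q_tu
  switch(model$structure,
    base = base,
    population = update_tumor_params(base, q_tu = model$q_tu,
                                     l_tu = lymph_ratio * model$q_tu,
                                     sigma_v = model$sigma_v),
    {
      lp <- covariate_predictor(model, ktrans, vp)
      if (lp$q < 0 || lp$sigma < 0) abort("negative linear predictor")
      if (lp$q == 0) {
        abort("subject unpredictable: covariate predictor is zero, so Q_TU = 0 under the slope model")
      }
      update_tumor_params(base,
                          q_tu = lp$q,
                          l_tu = lymph_ratio * lp$q,
                          sigma_v = 1 / (1 + lp$sigma))
    }
  )
}

#' Population-fitting settings
#'
#' @param n_starts Number of multi-start optimizations (jittered initial
#'   values, seeded and reproducible).
#' @param seed Base seed for the start jitter.
#' @param jitter_sd Standard deviation (log scale) of the start jitter.
#' @param maxit,reltol Nelder-Mead control parameters.
#' @param rtol ODE solver relative tolerance used inside the likelihood.
#' @param prior_sd Log-scale standard deviation of the weakly-informative
#'   shrinkage applied to the fitted fixed effects around their physiological
#'   initial values (default one order of magnitude, `log(10)`). The flow and
#'   permeability slopes share an identifiability ridge — as the sigma slope
#'   approaches zero the wall is fully reflective for every subject and only
#'   the product of the two slopes is determined by terminal observations —
#'   so unpenalized maximum likelihood can run to arbitrarily extreme slope
#'   pairs on some noisy cohorts. The penalty is negligible within an order
#'   of magnitude of the initial values and rules the ridge endpoints out;
#'   set `prior_sd = Inf` for pure maximum likelihood. Reported
#'   log-likelihoods and AIC are always the unpenalized likelihood at the
#'   estimate.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(n_starts = 2, seed = 1, jitter_sd = 0.3,
                         maxit = 500, reltol = 1e-10, rtol = 1e-8,
                         prior_sd = log(10)) {
  structure(list(n_starts = n_starts, seed = seed, jitter_sd = jitter_sd,
                 maxit = maxit, reltol = reltol, rtol = rtol,
                 prior_sd = prior_sd),
            class = "fit_settings")
}

# predicted terminal tumor concentration for each cohort row under a model;
# all subjects are integrated as one block-diagonal system (see tumor_batch)
predict_terminal <- function(model, cohort, base, plasma, rtol = 1e-8) {
  pars <- purrr::pmap(
    list(cohort$ktrans, cohort$vp, cohort$egfr_conc),
    function(k, v, egfr) {
      apply_covariates(model, k, v, update_tumor_params(base, c_egfr = egfr))
    }
  )
  if (is.null(plasma$curve)) {
    simulate_tumor_batch(pars, plasma, cohort$terminal_time * 60, rtol = rtol)
  } else {
    purrr::map2_dbl(pars, cohort$terminal_time,
                    ~ tumor_conc_at(.x, plasma, .y * 60, rtol = rtol))
  }
}

# profiled negative log-likelihood machinery (lognormal proportional error):
# sigma^2 is profiled out, leaving n/2 * log(mean squared log-residual)
profiled_nll <- function(obs, pred) {
  if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
  r <- log(obs) - log(pred)
  length(r) / 2 * log(max(mean(r^2), 1e-30))
}

full_loglik <- function(obs, pred) {
  r <- log(obs) - log(pred)
  s2 <- max(mean(r^2), 1e-30)
  -sum(log(obs)) - length(r) / 2 * (log(2 * pi * s2) + 1)
}

# parameter transforms between the optimizer scale and a covariate_model
par_to_model <- function(par, structure, error_cv = 0.2) {
  switch(structure,
    population = covariate_model("population", q_tu = exp(par[1]),
                                 sigma_v = stats::plogis(par[2]),
                                 error_cv = error_cv),
    ktrans = covariate_model("ktrans", theta_q = exp(par[1]),
                             theta_sigma = exp(par[2]), error_cv = error_cv),
    vp = covariate_model("vp", theta_q = exp(par[1]), theta_sigma = exp(par[2]),
                         error_cv = error_cv),
    ktrans_vp = covariate_model("ktrans_vp", theta_q = exp(par[1:2]),
                                theta_sigma = exp(par[3:4]), error_cv = error_cv)
  )
}

initial_par <- function(structure, cohort, base) {
  mk <- mean(cohort$ktrans)
  mv <- mean(cohort$vp)
  s0 <- (1 / base$sigma_v - 1)                 # sigma predictor at base value
  switch(structure,
    population = c(log(base$q_tu), stats::qlogis(base$sigma_v)),
    ktrans = log(c(base$q_tu / mk, s0 / mk)),
    vp = log(c(base$q_tu / max(mv, 1e-4), s0 / max(mv, 1e-4))),
    ktrans_vp = log(c(base$q_tu / (2 * mk), base$q_tu / (2 * max(mv, 1e-4)),
                      s0 / (2 * mk), s0 / (2 * max(mv, 1e-4))))
  )
}

#' Fit a covariate structure to a non-binding-antibody cohort
#'
#' Maximum-likelihood estimation of the covariate slopes (or, for the
#' `population` structure, of shared `Q_TU` and `sigma_v`) from the terminal
#' tumor observations of a non-binding-antibody cohort. Each subject's
#' prediction is the PBPK-simulated total tumor concentration at that
#' subject's terminal time, with subject parameters from [apply_covariates()].
#' Observations follow a proportional (lognormal) error model whose variance
#' is profiled out analytically; the remaining fixed effects are optimized by
#' Nelder-Mead on the log/logit scale with seeded multi-start.
#'
#' @param cohort Cohort tibble (one row per subject) with columns `ktrans`,
#'   `vp`, `terminal_time` (h), `observed_tumor_conc` (M), `egfr_conc` (must
#'   be 0: the training arm is non-binding), plus identifiers.
#' @param structure Covariate structure (see [covariate_model()]).
#' @param base Base [tumor_params()].
#' @param plasma A [plasma_pk()] for the non-binding antibody.
#' @param settings A [fit_settings()].
#' @return An object of class `covariate_fit`: the estimated
#'   [covariate_model()], `loglik`, `n_params` (fitted fixed effects + 1 error
#'   parameter), `aic = -2 loglik + 2 n_params`, `sigma` (residual SD, log
#'   scale), a per-subject `predictions` tibble, and convergence diagnostics.
#' @export
fit_population <- function(cohort, structure, base, plasma,
                           settings = fit_settings()) {
  stopifnot(is.data.frame(cohort), inherits(base, "tumor_params"),
            inherits(plasma, "plasma_pk"))
  structure <- match.arg(structure, c("base", "population", "ktrans", "vp", "ktrans_vp"))
  need <- c("ktrans", "vp", "terminal_time", "observed_tumor_conc", "egfr_conc")
  if (!all(need %in% names(cohort))) {
    abort(paste("cohort must have columns:", paste(need, collapse = ", ")))
  }
  if (any(cohort$egfr_conc != 0)) {
    abort("fit_population requires a non-binding-antibody cohort (egfr_conc = 0)")
  }
  if (structure %in% c("ktrans", "ktrans_vp") && any(!is.finite(cohort$ktrans))) {
    abort("structure uses Ktrans but the cohort has missing Patlak fits")
  }
  if (structure %in% c("vp", "ktrans_vp") && any(!is.finite(cohort$vp))) {
    abort("structure uses Vp but the cohort has missing Patlak fits")
  }
  obs <- cohort$observed_tumor_conc
  if (any(obs <= 0)) abort("observed tumor concentrations must be positive")

  finish <- function(model, par, convergence) {
    pred <- predict_terminal(model, cohort, base, plasma, rtol = settings$rtol)
    ll <- full_loglik(obs, pred)
    r <- log(obs) - log(pred)
    sigma <- sqrt(max(mean(r^2), 0))
    n_par <- length(par) + 1                   # + residual error parameter
    model$error_cv <- sqrt(exp(sigma^2) - 1)
    preds <- tibble::tibble(
      subject_id = cohort$subject_id %||% seq_len(nrow(cohort)),
      group = cohort$group %||% NA_character_,
      terminal_time = cohort$terminal_time,
      observed = obs, predicted = pred
    )
    base::structure(
      list(model = model, structure = structure, loglik = ll, n_params = n_par,
           aic = -2 * ll + 2 * n_par, sigma = sigma, predictions = preds,
           convergence = convergence, cohort_n = nrow(cohort), base = base,
           plasma = plasma, settings = settings),
      class = "covariate_fit"
    )
  }

  if (structure == "base") {
    return(finish(covariate_model("base"), numeric(), tibble::tibble()))
  }

  objective <- function(par) {
    # keep the search inside a generous but finite box: runaway slope values
    # (many orders of magnitude from any plausible physiology) only stiffen
    # the ODEs without improving the fit
    if (any(!is.finite(par)) || any(par > p0 + 12) || any(par < p0 - 12)) {
      return(1e10)
    }
    model <- par_to_model(par, structure)
    pred <- try(predict_terminal(model, cohort, base, plasma, rtol = settings$rtol),
                silent = TRUE)
    if (inherits(pred, "try-error")) return(1e10)
    penalty <- if (is.finite(settings$prior_sd)) {
      sum(((par - p0) / settings$prior_sd)^2) / 2
    } else 0
    profiled_nll(obs, pred) + penalty
  }

  p0 <- initial_par(structure, cohort, base)
  starts <- withr::with_seed(settings$seed, {
    lapply(seq_len(settings$n_starts), function(i) {
      if (i == 1) p0 else p0 + rnorm(length(p0), sd = settings$jitter_sd)
    })
  })
  runs <- lapply(seq_along(starts), function(i) {
    opt <- optim(starts[[i]], objective, method = "Nelder-Mead",
                 control = list(maxit = settings$maxit, reltol = settings$reltol))
    tibble::tibble(start = i, value = opt$value, convergence = opt$convergence,
                   par = list(opt$par))
  })
  runs <- dplyr::bind_rows(runs)
  # a run that exhausted maxit (code 1) on a near-perfect fit still carries a
  # valid optimum; only abort when every start failed to reach a finite value
  if (all(runs$value >= 1e9)) {
    abort(sprintf("fit_population did not converge in %d start(s)", settings$n_starts))
  }
  if (all(runs$convergence != 0)) {
    warn("optimizer reached its iteration limit in every start; using the best value found")
  }
  best <- runs$par[[which.min(runs$value)]]
  finish(par_to_model(best, structure), best, dplyr::select(runs, -"par"))
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat(sprintf("<covariate_fit> structure = %s, n = %d\n", x$structure, x$cohort_n))
  cat(sprintf("  loglik = %.3f, params = %d, AIC = %.2f, sigma = %.3f\n",
              x$loglik, x$n_params, x$aic, x$sigma))
  print(x$model)
  invisible(x)
}

#' Predict a target-binding antibody's tumor kinetics a priori
#'
#' Uses covariate relationships established on a non-binding-antibody cohort
#' to predict, without any refitting, the tumor concentration-time profile of
#' a target-binding antibody in one subject from that subject's own MRI
#' parameters: the fitted model supplies `Q_TU` and `sigma_v`, while the
#' group's EGFR expression switches on target-mediated disposition.
#'
#' @param fit A `covariate_fit` from [fit_population()] (or a
#'   [covariate_model()] with known slopes).
#' @param ktrans,vp The subject's MRI parameters.
#' @param base Base [tumor_params()] with the group `c_egfr` already set.
#' @param plasma A [plasma_pk()] for the target-binding antibody.
#' @param t_grid Output times (min); defaults to 6 simulated days.
#' @return A `pbpk_sim` object (see [simulate_tumor_pbpk()]).
#' @export
predict_individual <- function(fit, ktrans, vp, base, plasma,
                               t_grid = seq(0, 8640, by = 30)) {
  model <- if (inherits(fit, "covariate_fit")) fit$model else fit
  stopifnot(inherits(model, "covariate_model"))
  pars <- apply_covariates(model, ktrans, vp, base)
  simulate_tumor_pbpk(pars, plasma, t_grid)
}

#' A priori predictions for a whole target-binding cohort
#'
#' Vectorized [predict_individual()] at each subject's terminal time,
#' returning a prediction table ready for [mean_prediction_error()].
#'
#' @param fit A `covariate_fit` or `covariate_model`.
#' @param cohort Target-binding cohort tibble with `subject_id`, `group`,
#'   `ktrans`, `vp`, `terminal_time` (h), `observed_tumor_conc`, `egfr_conc`.
#' @param base Base [tumor_params()] (group EGFR taken from the cohort's
#'   `egfr_conc` column).
#' @param plasma A [plasma_pk()] for the target-binding antibody.
#' @param rtol ODE relative tolerance.
#' @return Tibble: `subject_id`, `group`, `terminal_time`, `observed`,
#'   `predicted`.
#' @export
predict_cohort <- function(fit, cohort, base, plasma, rtol = 1e-8) {
  model <- if (inherits(fit, "covariate_fit")) fit$model else fit
  stopifnot(inherits(model, "covariate_model"))
  pred <- predict_terminal(model, cohort, base, plasma, rtol = rtol)
  tibble::tibble(
    subject_id = cohort$subject_id %||% seq_len(nrow(cohort)),
    group = cohort$group %||% NA_character_,
    terminal_time = cohort$terminal_time,
    observed = cohort$observed_tumor_conc,
    predicted = pred
  )
}
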