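#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Patlak fit
#'
#' @param x A `patlak_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("ktrans", "vp"), estimate = c(x$ktrans, x$vp),
                 unit = c("1/min", ""))
}

#' @rdname tidy.patlak_fit
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_points = x$n_points, converged = x$converged,
                 active_constraints = x$active_constraints)
}

#' Tidy a fitted covariate model
#'
#' @param x A `covariate_fit` from [fit_population()].
#' @param ... Unused.
#' @return One row per fitted fixed effect.
#' @export
tidy.covariate_fit <- function(x, ...) {
  m <- x$model
  switch(x$structure,
    base = tibble::tibble(term = character(), estimate = numeric(), unit = character()),
    population = tibble::tibble(term = c("q_tu", "sigma_v"),
                                estimate = c(m$q_tu, m$sigma_v),
                                unit = c("L/min", "")),
    {
      cov <- switch(x$structure, ktrans = "ktrans", vp = "vp",
                    ktrans_vp = c("ktrans", "vp"))
      tibble::tibble(
        term = c(paste0("theta_q.", cov), paste0("theta_sigma.", cov)),
        estimate = c(m$theta_q, m$theta_sigma),
        unit = rep(c("L", "min"), each = length(cov))
      )
    }
  )
}

#' @rdname tidy.covariate_fit
#' @export
glance.covariate_fit <- function(x, ...) {
  tibble::tibble(structure = x$structure, loglik = x$loglik,
                 n_params = x$n_params, aic = x$aic, sigma = x$sigma,
                 n = x$cohort_n)
}

#' Plot a tumor PBPK simulation
#'
#' Plasma and total tumor concentration versus time on a log concentration
#' scale.
#'
#' @param object A `pbpk_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpk_sim <- function(object, ...) {
  tr <- object$trajectory |>
    dplyr::select("time_min", "plasma_conc", "tumor_total_conc") |>
    tidyr::pivot_longer(-"time_min", names_to = "space", values_to = "conc") |>
    dplyr::mutate(space = dplyr::recode(.data$space,
                                        plasma_conc = "plasma",
                                        tumor_total_conc = "tumor (total)"))
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_min / 1440, .data$conc,
                                   colour = .data$space)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "concentration (M)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot
#'
#' Scatter of predicted against observed terminal tumor concentrations with
#' the line of unity, the standard diagnostic for prediction tables.
#'
#' @param table Prediction table with `observed`, `predicted`, and optionally
#'   `group`.
#' @return A ggplot.
#' @export
plot_obs_pred <- function(table) {
  stopifnot(all(c("observed", "predicted") %in% names(table)))
  aes <- if ("group" %in% names(table)) {
    ggplot2::aes(.data$observed, .data$predicted, colour = .data$group)
  } else {
    ggplot2::aes(.data$observed, .data$predicted)
  }
  ggplot2::ggplot(table, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed (M)", y = "predicted (M)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_obs_pred
#' @param object A `covariate_fit`.
#' @param ... Unused.
#' @export
autoplot.covariate_fit <- function(object, ...) {
  plot_obs_pred(object$predictions) +
    ggplot2::ggtitle(sprintf("structure: %s (AIC %.1f)", object$structure, object$aic))
}
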