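#' @importFrom rlang %||% abort warn
#' @importFrom stats approx optim optimize rnorm runif setNames median sd
#' @importFrom utils head tail
NULL

#' Trapezoidal integration on an arbitrary grid
#'
#' @param x Increasing sample locations.
#' @param y Sample values.
#' @return `trapz()` returns the integral; `cumtrapz()` the running integral
#'   (same length as `x`, starting at 0).
#' @export
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' @rdname trapz
#' @export
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# multiplicative lognormal noise with unit median and coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(rnorm(n, mean = 0, sd = sqrt(log(1 + cv^2))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}
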