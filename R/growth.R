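#' Linearly detrend a log population-size series
#'
#' Residuals of an OLS regression of `log(N)` on calendar year. Detrending
#' removes the gradual trend in carrying capacity (warmer summers, higher
#' plant productivity) so that the density covariate reflects deviation
#' from the trending equilibrium rather than the trend itself.
#'
#' @param n numeric vector of annual total population sizes (> 0).
#' @param year matching calendar years (default: consecutive).
#' @return numeric vector of residuals (sums to zero).
#' @export
detrend_log_n <- function(n, year = seq_along(n)) {
  stopifnot(length(n) >= 3L, all(n > 0), length(year) == length(n))
  stats::resid(stats::lm(log(n) ~ year))
}

#' Growth-rate regression with a ROS x density interaction
#'
#' Ordinary least squares of the annual log growth rate
#' `log(N[t+1]/N[t])` on detrended log density, ROS, winter length, and the
#' ROS x density interaction (all covariates for the winter between t and
#' t + 1). A companion factor fit replaces the continuous density with
#' empirical-tercile classes (low/medium/high) for visual contrasts.
#'
#' @param n numeric vector of annual total population sizes.
#' @param covariates data.frame `winter`, `ros`, `winter_length`; row t must
#'   describe the winter driving the t to t + 1 transition.
#' @param year calendar years of `n` (default consecutive).
#' @return object of class `growth_reg` with elements `fit` (the `lm`),
#'   `factor_fit` (terciles), `data` (the model frame) and `coefficients`.
#' @export
fit_growth_regression <- function(n, covariates, year = seq_along(n)) {
  stopifnot(length(n) >= 11L)
  nt <- length(n) - 1L
  d <- data.frame(
    growth = log(n[-1] / n[-length(n)]),
    n_det = detrend_log_n(n, year)[-length(n)],
    ros = covariates$ros[seq_len(nt)],
    winter_length = covariates$winter_length[seq_len(nt)]
  )
  fit <- stats::lm(growth ~ n_det + ros + winter_length + ros:n_det, data = d)
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("singular design in growth regression")
  d$n_class <- cut(d$n_det,
                   breaks = stats::quantile(d$n_det, c(0, 1/3, 2/3, 1)),
                   labels = c("low", "medium", "high"),
                   include.lowest = TRUE)
  factor_fit <- stats::lm(growth ~ n_class + ros + winter_length +
                            ros:n_class, data = d)
  structure(list(fit = fit, factor_fit = factor_fit, data = d,
                 coefficients = stats::coef(fit)),
            class = "growth_reg")
}

#' @export
coef.growth_reg <- function(object, ...) object$coefficients

#' @export
print.growth_reg <- function(x, ...) {
  cat("Growth-rate regression: growth ~ detrended log N * ROS + winter length\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.growth_reg <- function(object, ...) summary(object$fit)
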