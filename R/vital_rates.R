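#' Density-dependent ROS transform
#'
#' The ROS covariate entering the vital-rate models is
#' `ROS' = ROS * exp(k * N_posthunt)`. Because the multiplier is strictly
#' positive, the fitted ROS effect keeps one sign across all population
#' sizes; `k > 0` amplifies the effect at high density (the icing/forage
#' competition interaction), `k < 0` dampens it, `k = 0` removes the
#' interaction. The exponent is capped at +/-50 to guard overflow during
#' the k search.
#'
#' @param ros log-scale ROS value(s), >= 0.
#' @param n_posthunt post-hunt female population size(s), individuals.
#' @param k interaction shape, units 1/individuals.
#' @return transformed covariate, same sign as `ros`.
#' @examples
#' ros_prime(2, 1000, -0.001)  # 2 * exp(-1)
#' @export
ros_prime <- function(ros, n_posthunt, k) {
  ros * exp(pmin(pmax(k * n_posthunt, -50), 50))
}

# age-class labels for the two rate panels
SURV_CLASSES <- c("0", "1", "2", "3-8", "9-11", "12+")
FEC_CLASSES  <- c("1", "2", "3-8", "9-11", "12+")

rate_classes <- function(rate_type) {
  if (rate_type == "S") SURV_CLASSES else FEC_CLASSES
}

# assemble the per-observation model frame for one rate type at a given k
vrm_frame <- function(panel, covariates, n_posthunt, rate_type, clamp_eps) {
  p <- panel[panel$rate_type == rate_type, ]
  classes <- rate_classes(rate_type)
  if (!all(p$age_class %in% seq_along(classes)))
    stop("age_class out of range for rate type ", rate_type)
  years <- sort(unique(p$year))
  if (length(years) < 10L)
    stop("need at least 10 years of panel data, got ", length(years))
  cov_idx <- match(p$year, covariates$winter)
  np_idx <- match(p$year, n_posthunt$year)
  if (anyNA(cov_idx)) stop("covariates missing for some panel years")
  if (anyNA(np_idx)) stop("n_posthunt missing for some panel years")
  data.frame(
    y = logit(clamp_rates(p$value, clamp_eps)),
    cls = factor(classes[p$age_class], levels = classes),
    year = p$year,
    year_f = factor(p$year),
    ros = covariates$ros[cov_idx],
    wl = covariates$winter_length[cov_idx],
    n_post = n_posthunt$n_posthunt[np_idx]
  )
}

fit_one_k <- function(df, k, n_scaling, year_center) {
  df$rosp <- ros_prime(df$ros, df$n_post, k)
  df$n_scaled <- (df$n_post - n_scaling[1]) / n_scaling[2]
  df$year_c <- df$year - year_center
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ cls + n_scaled + year_c + rosp + winter_length + cls:rosp +
        (1 | year_f),
      data = transform(df, winter_length = wl),
      REML = FALSE, control = ctrl)),
    error = function(e) NULL)
  fit
}

# AIC profile over k: grid pre-scan, then golden-section refinement on the
# bracketing interval around the grid minimum
search_k <- function(df, k_bounds, k_grid, n_scaling, year_center) {
  grid <- seq(k_bounds[1], k_bounds[2], length.out = k_grid)
  aic <- function(k) {
    f <- fit_one_k(df, k, n_scaling, year_center)
    if (is.null(f)) {
      warning(sprintf("model fit failed at k = %g; candidate skipped", k))
      return(Inf)
    }
    stats::AIC(f)
  }
  aics <- vapply(grid, aic, 0)
  if (all(!is.finite(aics))) stop("vital-rate model failed at every candidate k")
  i <- which.min(aics)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(aic, lower = lo, upper = hi,
                         tol = diff(k_bounds) * 1e-4)
  if (opt$objective <= aics[i]) {
    list(k = opt$minimum, aic = opt$objective, grid = grid, grid_aic = aics)
  } else {
    list(k = grid[i], aic = aics[i], grid = grid, grid_aic = aics)
  }
}

# slim per-rate summary kept inside a vrm object
slim_rate_fit <- function(fit, df, k, aic) {
  classes <- levels(df$cls)
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$year_f
  ranef_year <- stats::setNames(re[, 1], rownames(re))
  res <- stats::residuals(fit)
  years <- sort(unique(df$year))
  rmat <- matrix(NA_real_, length(classes), length(years),
                 dimnames = list(classes, years))
  rmat[cbind(match(as.character(df$cls), classes),
             match(df$year, years))] <- res
  # per-class intercepts and ROS' slopes (treatment contrasts resolved),
  # precomputed for fast evaluation in projection loops
  a_cls <- fe[["(Intercept)"]] +
    c(0, unname(fe[paste0("cls", classes[-1])]))
  b_ros_cls <- fe[["rosp"]] +
    c(0, unname(fe[paste0("cls", classes[-1], ":rosp")]))
  names(a_cls) <- names(b_ros_cls) <- classes
  list(k = k, aic = aic, fixef = fe, ranef_year = ranef_year,
       residuals = rmat, classes = classes,
       a_cls = a_cls, b_ros_cls = b_ros_cls,
       b_n = fe[["n_scaled"]], b_year = fe[["year_c"]],
       b_wl = fe[["winter_length"]],
       sigma_resid = stats::sigma(fit),
       var_year = as.numeric(lme4::VarCorr(fit)$year_f))
}

#' Fit density-dependent vital-rate models for one posterior sample
#'
#' Fits the survival and fecundity regressions on the logit scale with
#' age-class intercepts, scaled post-hunt population size, a linear year
#' trend, the density-dependent ROS transform `ROS' = ROS * exp(k * N)` with
#' an age-class interaction, winter length, and a random year intercept
#' (linear mixed model, maximum likelihood). The interaction shape `k` is
#' estimated separately for each rate by minimising AIC over
#' `k_bounds` (41-point grid pre-scan plus golden-section refinement).
#' The 11x11 environmental covariance of annual vital-rate deviations
#' (random year effect + residual, 6 survival + 5 fecundity classes) is
#' estimated as part of the fit.
#'
#' @param panel long data.frame with columns `year`, `rate_type` (`"S"` or
#'   `"F"`), `age_class` (1-based index into the 6 survival / 5 fecundity
#'   classes) and `value` (rate in (0,1)); one posterior sample.
#' @param covariates data.frame with columns `winter`, `ros`,
#'   `winter_length` (see [winter_covariates()]).
#' @param n_posthunt data.frame with columns `year`, `n_posthunt` (female
#'   population size after the hunting season).
#' @param k_bounds numeric length-2 search interval for `k`
#'   (1/individuals).
#' @param k_grid number of grid points in the pre-scan.
#' @param clamp_eps boundary clamp for rates before the logit transform.
#' @return object of class `vrm`: per-rate fits (`survival`, `fecundity`,
#'   each with `k`, `aic`, `fixef`, `ranef_year`, `residuals`), the scaling
#'   constants (`n_scaling`, `year_center`), training `years`, and the
#'   environmental covariance `sigma`.
#' @seealso [predict.vrm()], [simulate.vrm()], [estimate_sigma()]
#' @export
fit_vital_rates <- function(panel, covariates, n_posthunt,
                            k_bounds = c(-0.01, 0.01), k_grid = 41,
                            clamp_eps = 1e-6) {
  stopifnot(length(k_bounds) == 2, k_bounds[1] < k_bounds[2])
  if (is.numeric(n_posthunt) && !is.null(names(n_posthunt)))
    n_posthunt <- data.frame(year = as.integer(names(n_posthunt)),
                             n_posthunt = as.numeric(n_posthunt))
  dfs <- vrm_frame(panel, covariates, n_posthunt, "S", clamp_eps)
  dff <- vrm_frame(panel, covariates, n_posthunt, "F", clamp_eps)
  np_years <- dfs$n_post[!duplicated(dfs$year)]
  n_scaling <- c(mean = mean(np_years), sd = stats::sd(np_years))
  year_center <- mean(range(dfs$year))

  out <- list(n_scaling = n_scaling, year_center = year_center,
              years = sort(unique(dfs$year)), k_bounds = k_bounds)
  for (rt in c("S", "F")) {
    df <- if (rt == "S") dfs else dff
    ks <- search_k(df, k_bounds, k_grid, n_scaling, year_center)
    fit <- fit_one_k(df, ks$k, n_scaling, year_center)
    if (is.null(fit)) stop("final fit failed for rate type ", rt)
    slim <- slim_rate_fit(fit, df, ks$k, ks$aic)
    slim$k_profile <- data.frame(k = ks$grid, aic = ks$grid_aic)
    out[[if (rt == "S") "survival" else "fecundity"]] <- slim
  }
  out <- structure(out, class = "vrm")
  out$sigma <- estimate_sigma(out)
  out
}

#' Environmental covariance of annual vital-rate deviations
#'
#' For every training year, the environmental deviation of each of the 11
#' class-rates (6 survival + 5 fecundity) on the logit scale is the random
#' year intercept plus the residual of the fitted model. The returned matrix
#' is the sample covariance of these 11-dimensional annual vectors,
#' projected to the nearest positive semi-definite matrix if sampling noise
#' breaks PSD.
#'
#' @param object a fitted [fit_vital_rates()] model.
#' @return symmetric PSD 11x11 covariance matrix with named dimensions
#'   (`S_<class>`, `F_<class>`).
#' @export
estimate_sigma <- function(object) {
  stopifnot(inherits(object, "vrm"))
  yrs <- as.character(object$years)
  if (length(yrs) < 2L) stop("need at least 2 years to estimate sigma")
  dev_block <- function(part, prefix) {
    d <- part$residuals[, yrs, drop = FALSE] +
      rep(part$ranef_year[yrs], each = nrow(part$residuals))
    rownames(d) <- paste0(prefix, rownames(d))
    d
  }
  dev <- rbind(dev_block(object$survival, "S_"),
               dev_block(object$fecundity, "F_"))
  if (anyNA(dev)) stop("incomplete class-year residual matrix")
  nearest_psd(stats::cov(t(dev)))
}

#' Draw multivariate-normal environmental deviates
#'
#' i.i.d. rows from `MVN(0, sigma)`; one row per projection year, one
#' column per class-rate (6 survival + 5 fecundity), applied on the logit
#' scale.
#'
#' @param sigma PSD covariance matrix (e.g. `fit$sigma`).
#' @param n_draws number of rows.
#' @param seed optional integer seed.
#' @return `n_draws x ncol(sigma)` matrix.
#' @export
sample_env_deviates <- function(sigma, n_draws, seed = NULL) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("sigma is not positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  m <- MASS::mvrnorm(n_draws, mu = rep(0, ncol(sigma)),
                     Sigma = nearest_psd(sigma))
  if (n_draws == 1L) m <- matrix(m, nrow = 1)
  colnames(m) <- colnames(sigma)
  m
}

# per-class linear predictor on the logit scale for one rate part
vrm_linpred <- function(part, ros, wl, n_posthunt, year, n_scaling,
                        year_center) {
  rosp <- ros_prime(ros, n_posthunt, part$k)
  nsc <- (n_posthunt - n_scaling[[1]]) / n_scaling[[2]]
  part$a_cls + part$b_n * nsc + part$b_year * (year - year_center) +
    part$b_wl * wl + part$b_ros_cls * rosp
}

#' Predict age-class vital rates from a fitted model
#'
#' Evaluates the fitted linear predictors at the supplied covariates (using
#' the model's estimated `k` and stored scaling constants), optionally adds
#' an environmental deviate on the logit scale, and back-transforms through
#' the logistic function, so all rates lie strictly in (0, 1).
#'
#' @param object a fitted [fit_vital_rates()] model.
#' @param ros log-scale ROS value of the winter ending in `year`.
#' @param winter_length winter length in days.
#' @param n_posthunt post-hunt female population size.
#' @param year calendar year (the linear trend covariate; freeze it at the
#'   last training year for long projections).
#' @param deviate optional 11-vector of environmental deviates (order:
#'   6 survival then 5 fecundity classes), e.g. a row of
#'   [sample_env_deviates()].
#' @param ... unused.
#' @return list with numeric vectors `survival` (6 classes) and `fecundity`
#'   (5 classes).
#' @export
predict.vrm <- function(object, ros, winter_length, n_posthunt, year,
                        deviate = NULL, ...) {
  lp_s <- vrm_linpred(object$survival, ros, winter_length, n_posthunt, year,
                      object$n_scaling, object$year_center)
  lp_f <- vrm_linpred(object$fecundity, ros, winter_length, n_posthunt, year,
                      object$n_scaling, object$year_center)
  if (!is.null(deviate)) {
    stopifnot(length(deviate) == 11L)
    lp_s <- lp_s + deviate[1:6]
    lp_f <- lp_f + deviate[7:11]
  }
  list(survival = inv_logit(lp_s), fecundity = inv_logit(lp_f))
}

#' Simulate environmental deviate matrices from a fitted model
#'
#' Convenience wrapper around [sample_env_deviates()] using the model's own
#' covariance.
#'
#' @param object a fitted [fit_vital_rates()] model.
#' @param nsim number of years (rows) per draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return `nsim x 11` deviate matrix.
#' @export
simulate.vrm <- function(object, nsim = 1, seed = NULL, ...) {
  sample_env_deviates(object$sigma, nsim, seed = seed)
}

#' @export
coef.vrm <- function(object, ...) {
  list(survival = object$survival$fixef, fecundity = object$fecundity$fixef,
       k = c(survival = object$survival$k, fecundity = object$fecundity$k))
}

#' @export
print.vrm <- function(x, ...) {
  cat("Density-dependent vital-rate model (logit-linear mixed, ML)\n")
  cat(sprintf("  years: %d-%d (%d), N scaling: mean %.0f, sd %.0f\n",
              min(x$years), max(x$years), length(x$years),
              x$n_scaling[[1]], x$n_scaling[[2]]))
  cat(sprintf("  survival : k = %+.5f (AIC %.1f)\n",
              x$survival$k, x$survival$aic))
  cat(sprintf("  fecundity: k = %+.5f (AIC %.1f)\n",
              x$fecundity$k, x$fecundity$aic))
  cat(sprintf("  ROS' slope (ref class): S %+.3f, F %+.3f\n",
              x$survival$fixef[["rosp"]], x$fecundity$fixef[["rosp"]]))
  invisible(x)
}

#' @export
summary.vrm <- function(object, ...) {
  s <- object$survival; f <- object$fecundity
  out <- list(
    k = c(survival = s$k, fecundity = f$k),
    aic = c(survival = s$aic, fecundity = f$aic),
    fixef = list(survival = s$fixef, fecundity = f$fixef),
    var_year = c(survival = s$var_year, fecundity = f$var_year),
    sigma_diag = diag(object$sigma))
  class(out) <- "summary.vrm"
  out
}

#' @export
print.summary.vrm <- function(x, ...) {
  cat("Vital-rate model summary\n  k:", sprintf("%+.5f", x$k), "\n")
  cat("  AIC:", sprintf("%.1f", x$aic), "\n")
  cat("  random-year variance:", sprintf("%.4f", x$var_year), "\n")
  cat("  sigma diagonal (logit scale):\n")
  print(round(x$sigma_diag, 4))
  invisible(x)
}
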