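#' Ground-truth preset for the synthetic study system
#'
#' Returns the generating model for all synthetic data: a fully specified
#' density-dependent vital-rate model (the "truth" the fitting machinery is
#' asked to recover), the environmental covariance of annual deviations, a
#' High-Arctic weather regime, an initial age structure and removal
#' intensities. The preset is calibrated so that (i) ROS effects are
#' negative for every class, strongest in calves and the oldest females and
#' weakest in prime-aged (3-8) females, (ii) the effect is amplified at
#' high density (`k_true > 0` in `ROS' = ROS * exp(k N)`), (iii) the
#' unperturbed deterministic population equilibrates near N = 1800 under
#' mean covariates, and (iv) a single extreme winter (log ROS = 4.2) at
#' high density crashes the population by tens of percent.
#'
#' @return list of class `ground_truth` with elements `model` (a `vrm`
#'   usable with [predict.vrm()] and [project_population()]), `weather`
#'   (regime parameters), `init_state`, `removal_rates`, `obs_noise_sd`.
#' @export
ground_truth_preset <- function() {
  wl_ref <- 210
  n_scaling <- c(mean = 1500, sd = 300)
  year_center <- 2004.5

  make_part <- function(base_rates, b_ros_cls, b_n, b_year, b_wl, k,
                        classes) {
    a_cls <- logit(base_rates) - b_wl * wl_ref
    names(a_cls) <- names(b_ros_cls) <- classes
    list(k = k, a_cls = a_cls, b_ros_cls = b_ros_cls, b_n = b_n,
         b_year = b_year, b_wl = b_wl, classes = classes)
  }
  surv <- make_part(
    base_rates = c(0.84, 0.92, 0.945, 0.955, 0.90, 0.78),
    b_ros_cls = c(-0.042, -0.019, -0.0126, -0.0095, -0.019, -0.042),
    b_n = -0.50, b_year = 0.015, b_wl = -0.004, k = 0.002,
    classes = SURV_CLASSES)
  fec <- make_part(
    base_rates = c(0.06, 0.35, 0.84, 0.72, 0.42),
    b_ros_cls = c(-0.035, -0.031, -0.0175, -0.031, -0.052),
    b_n = -0.70, b_year = 0.015, b_wl = -0.006, k = 0.002,
    classes = FEC_CLASSES)

  # environmental covariance: larger year-to-year variation in young/old
  # classes, moderate positive correlation within and across rate types
  sds <- c(0.35, 0.25, 0.18, 0.15, 0.25, 0.40,  # survival classes
           0.34, 0.30, 0.23, 0.27, 0.34)        # fecundity classes
  R <- matrix(0.3, 11, 11)
  R[1:6, 1:6] <- 0.5
  R[7:11, 7:11] <- 0.5
  diag(R) <- 1
  sigma <- nearest_psd(diag(sds) %*% R %*% diag(sds))
  nm <- c(paste0("S_", SURV_CLASSES), paste0("F_", FEC_CLASSES))
  dimnames(sigma) <- list(nm, nm)

  model <- structure(list(survival = surv, fecundity = fec,
                          n_scaling = n_scaling, year_center = year_center,
                          years = 1994:2014, sigma = sigma),
                     class = "vrm")
  structure(list(
    model = model,
    weather = list(temp_mean = -4, temp_amplitude = 10, temp_peak_doy = 196,
                   noise_sd = 3, noise_rho = 0.7,
                   wet_day_prob = 0.25, wet_day_shape = 0.7,
                   wet_day_scale = 3,
                   warm_events_shape = 0.6, warm_events_scale = 1.8,
                   warm_temp_range = c(1, 3.5),
                   warm_precip_shape = 0.7, warm_precip_scale = 18),
    init_state = build_initial_state(950, 0.45),
    removal_rates = c(hunt = 0.012, cull = 0.004),
    obs_noise_sd = 0.20,
    n_obs_noise_sd = 0.05,
    wl_ref = wl_ref
  ), class = "ground_truth")
}

#' Generate a synthetic daily weather record
#'
#' Daily mean temperature follows a sinusoidal seasonal cycle with AR(1)
#' noise; ordinary precipitation falls on random wet days; in addition,
#' each winter (November-April) receives a random number of warm-spell
#' events (temperature forced above the ROS threshold with substantial
#' rain), whose overdispersed frequency drives a right-skewed per-winter
#' ROS distribution spanning roughly the observed range 0-4.2 on the log
#' scale.
#'
#' @param gt a [ground_truth_preset()] (its `weather` element is used).
#' @param winters integer vector of winter labels to cover; the record runs
#'   from 1 August before the first winter to 31 July of the last.
#' @param seed optional integer seed.
#' @return daily weather data.frame (`date`, `mean_temp`, `precip`).
#' @export
generate_weather <- function(gt, winters, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  w <- gt$weather
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-08-01", min(winters) - 1)),
               as.Date(sprintf("%d-07-31", max(winters))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  temp <- w$temp_mean +
    w$temp_amplitude * cos(2 * pi * (doy - w$temp_peak_doy) / 365.25)
  n <- length(dates)
  eps <- numeric(n)
  eps[1] <- stats::rnorm(1, 0, w$noise_sd)
  innov <- stats::rnorm(n, 0, w$noise_sd * sqrt(1 - w$noise_rho^2))
  for (i in 2:n) eps[i] <- w$noise_rho * eps[i - 1] + innov[i]
  temp <- temp + eps
  wet <- stats::runif(n) < w$wet_day_prob
  precip <- ifelse(wet, stats::rgamma(n, w$wet_day_shape,
                                      scale = w$wet_day_scale), 0)
  out <- data.frame(date = dates, mean_temp = temp, precip = precip)

  for (yr in winters) {
    win <- winter_window(yr)
    idx <- which(dates >= win[["start"]] & dates <= win[["end"]])
    lambda <- stats::rgamma(1, w$warm_events_shape,
                            scale = w$warm_events_scale)
    n_ev <- stats::rpois(1, lambda)
    if (n_ev > 0) {
      ev <- sample(idx, min(n_ev, length(idx)))
      out$mean_temp[ev] <- stats::runif(length(ev), w$warm_temp_range[1],
                                        w$warm_temp_range[2])
      out$precip[ev] <- out$precip[ev] +
        stats::rgamma(length(ev), w$warm_precip_shape,
                      scale = w$warm_precip_scale)
    }
  }
  out
}

#' Generate a posterior-ensemble-style demographic data set
#'
#' Simulates one "true" population trajectory through the projection engine
#' using the ground-truth vital-rate model (with multivariate-normal
#' environmental deviates and binomial demographic stochasticity), then
#' emits `n_samples` noisy replicates of the annual class rates
#' (logit-normal observation noise), emulating the spread of a posterior
#' sample ensemble, together with the observed age-structured counts,
#' removal schedule, per-winter covariates and post-hunt population sizes.
#'
#' @param gt a [ground_truth_preset()].
#' @param n_samples number of posterior-style replicates.
#' @param years calendar years of observed age structure; vital rates are
#'   emitted for the transitions between consecutive years.
#' @param seed optional integer seed.
#' @param obs_noise_sd logit-scale observation noise on rates (default from
#'   the preset; 0 makes every sample equal the truth).
#' @param n_obs_noise_sd log-scale noise on each sample's population sizes,
#'   emulating posterior uncertainty in N (default from the preset).
#' @return list with `panel` (long data.frame: `sample_id`, `year`,
#'   `rate_type`, `age_class`, `value`), `age_structure` (`year`, `age`,
#'   `count`; the posterior-mean counts), `removals` (`year`, `age`,
#'   `hunted`, `culled`), `covariates`, `n_posthunt` (`sample_id`, `year`,
#'   `n_posthunt`), `true_rates`, `truth` (the generating `vrm`), `weather`.
#' @export
generate_posterior_panel <- function(gt, n_samples, years = 1994:2015,
                                     seed = NULL, obs_noise_sd = NULL,
                                     n_obs_noise_sd = NULL) {
  stopifnot(inherits(gt, "ground_truth"), n_samples >= 1)
  obs_noise_sd <- obs_noise_sd %||% gt$obs_noise_sd
  n_obs_noise_sd <- n_obs_noise_sd %||% gt$n_obs_noise_sd %||% 0
  if (!is.null(seed)) set.seed(seed)
  rate_years <- years[-length(years)]
  weather <- generate_weather(gt, winters = range(years)[1]:range(years)[2])
  covariates <- winter_covariates(weather, min(years), max(years))

  truth <- gt$model
  truth$years <- rate_years

  st <- gt$init_state
  states <- matrix(0, length(years), N_AGES, dimnames = list(years, 0:13))
  states[1, ] <- st
  removals <- NULL
  n_posthunt <- numeric(length(rate_years))
  true_s <- matrix(NA_real_, 6, length(rate_years),
                   dimnames = list(SURV_CLASSES, rate_years))
  true_f <- matrix(NA_real_, 5, length(rate_years),
                   dimnames = list(FEC_CLASSES, rate_years))
  for (i in seq_along(rate_years)) {
    yr <- rate_years[i]
    h <- stats::rbinom(N_AGES, size = round(st), prob = gt$removal_rates["hunt"])
    cc <- stats::rbinom(N_AGES, size = round(st) - h,
                        prob = gt$removal_rates["cull"])
    rem <- list(hunted = h, culled = cc)
    removals <- rbind(removals,
                      data.frame(year = yr, age = 0:13, hunted = h,
                                 culled = cc))
    n_post <- sum(st) - sum(h) - sum(cc)
    n_posthunt[i] <- n_post
    cv <- covariates[covariates$winter == yr, ]
    dev <- drop(sample_env_deviates(truth$sigma, 1))
    rates <- predict(truth, ros = cv$ros, winter_length = cv$winter_length,
                     n_posthunt = n_post, year = yr, deviate = dev)
    true_s[, i] <- rates$survival
    true_f[, i] <- rates$fecundity
    ar <- expand_class_rates(rates)
    st <- step_population(st, ar$survival, ar$fecundity, rem,
                          mode = "stochastic")
    states[i + 1L, ] <- st
  }

  age_structure <- data.frame(
    year = rep(years, each = N_AGES),
    age = rep(0:13, length(years)),
    count = as.vector(t(states)))

  noisy <- function(true_mat, rate_type, sid) {
    nv <- length(true_mat)
    val <- inv_logit(logit(clamp_rates(as.vector(true_mat))) +
                       stats::rnorm(nv, 0, obs_noise_sd))
    data.frame(sample_id = sid,
               year = rep(rate_years, each = nrow(true_mat)),
               rate_type = rate_type,
               age_class = rep(seq_len(nrow(true_mat)), length(rate_years)),
               value = val)
  }
  panel <- do.call(rbind, lapply(seq_len(n_samples), function(sid) {
    rbind(noisy(true_s, "S", sid), noisy(true_f, "F", sid))
  }))
  # per-sample posterior spread on population size (log-normal per year)
  np <- do.call(rbind, lapply(seq_len(n_samples), function(sid) {
    data.frame(sample_id = sid, year = rate_years,
               n_posthunt = n_posthunt *
                 exp(stats::rnorm(length(rate_years), 0, n_obs_noise_sd)))
  }))

  list(panel = panel,
       age_structure = age_structure,
       removals = removals,
       covariates = covariates,
       n_posthunt = np,
       true_rates = list(survival = true_s, fecundity = true_f),
       truth = truth,
       weather = weather)
}
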