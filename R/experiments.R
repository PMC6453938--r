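#' Published scenario summaries for the Svalbard reindeer population
#'
#' Reference values of the five ROS-frequency scenario summaries reported
#' for the Svalbard wild reindeer study system (mean and variance of
#' population size, variance of the log growth rate, and quasi-/true-
#' extinction percentages over 100-year projections of the full
#' posterior-ensemble model). They serve as fixed inputs for contrast
#' arithmetic ([summarize_contrasts()]) and as a qualitative yardstick for
#' the synthetic-ensemble experiments; the absolute values depend on the
#' original field-data posterior ensemble and are not reproducible from
#' synthetic data.
#'
#' @return data.frame with columns `scenario`, `mean_n`, `var_n`,
#'   `var_growth`, `quasi_extinct_pct`, `true_extinct_pct`, plus fraction
#'   columns `p_quasi_extinct`, `p_extinct`.
#' @export
svalbard_scenario_reference <- function() {
  d <- data.frame(
    scenario = c("very_low", "low", "medium", "high", "very_high"),
    mean_n = c(1820, 1698, 1546, 1458, 1369),
    var_n = c(189040, 165458, 152002, 102965, 71090),
    var_growth = c(0.100, 0.099, 0.106, 0.079, 0.062),
    quasi_extinct_pct = c(4.65, 4.59, 4.10, 1.25, 0.41),
    true_extinct_pct = c(0.84, 0.45, 0.30, 0.02, 0.00002)
  )
  d$p_quasi_extinct <- d$quasi_extinct_pct / 100
  d$p_extinct <- d$true_extinct_pct / 100
  d
}

#' Stochastic 100-year scenario simulation
#'
#' For every model in the ensemble and every replicate: draws a ROS
#' sequence under the scenario (beta inverse-transform over the observed
#' pool), winter lengths from their observed normal distribution, and
#' multivariate-normal environmental deviates from the model's covariance;
#' then projects the population stochastically from the initial state.
#' Summaries are pooled over all model x replicate trajectories.
#'
#' @param models list of fitted [fit_vital_rates()] models (the posterior
#'   ensemble).
#' @param initial_state length-14 age vector.
#' @param scenario a [ros_scenario()].
#' @param pool observed ROS values (the empirical distribution to warp).
#' @param wl_mean,wl_sd winter-length mean and sd (days).
#' @param horizon projection length in years.
#' @param reps_per_model stochastic replicates per model.
#' @param quasi_threshold quasi-extinction threshold (strict `N <`).
#' @param seed integer seed (one stream drives the whole simulation).
#' @return list of class `scenario_summary`: `scenario`, `mean_n`, `var_n`,
#'   `var_growth` (pooled over finite log growth steps), `p_extinct`
#'   (fraction of trajectories reaching N = 0), `p_quasi_extinct` (fraction
#'   ever strictly below the threshold), `n_trajectories`, `horizon`.
#' @export
run_scenario <- function(models, initial_state, scenario, pool,
                         wl_mean, wl_sd, horizon = 100,
                         reps_per_model = 100, quasi_threshold = 100,
                         seed = NULL) {
  stopifnot(length(models) >= 1, inherits(scenario, "ros_scenario"))
  if (!is.null(seed)) set.seed(seed)
  q <- ros_quantile_fun(pool)
  n_traj <- length(models) * reps_per_model
  all_n <- vector("list", n_traj)
  extinct <- quasi <- logical(n_traj)
  growth_ss <- growth_s <- growth_n <- 0
  i <- 0L
  for (m in models) {
    for (r in seq_len(reps_per_model)) {
      i <- i + 1L
      ros <- q(stats::rbeta(horizon, scenario$alpha1, scenario$alpha2))
      wl <- sample_winter_length(wl_mean, wl_sd, horizon)
      dev <- sample_env_deviates(m$sigma, horizon)
      st <- project_population(m, initial_state, ros, wl, deviates = dev,
                               mode = "stochastic")
      tot <- attr(st, "total")[-1]  # years 1..horizon
      all_n[[i]] <- tot
      extinct[i] <- any(tot == 0)
      quasi[i] <- any(tot < quasi_threshold)
      g <- log(tot[-1] / tot[-length(tot)])
      g <- g[is.finite(g)]
      growth_ss <- growth_ss + sum(g^2)
      growth_s <- growth_s + sum(g)
      growth_n <- growth_n + length(g)
    }
  }
  pooled <- unlist(all_n)
  var_growth <- (growth_ss - growth_s^2 / growth_n) / (growth_n - 1)
  structure(list(scenario = scenario,
                 mean_n = mean(pooled), var_n = stats::var(pooled),
                 var_growth = var_growth,
                 p_extinct = mean(extinct), p_quasi_extinct = mean(quasi),
                 n_trajectories = n_traj, horizon = horizon),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (%d trajectories x %d years)\n  mean N %.0f, var N %.0f, var growth %.4f\n  P(extinct) %.4g, P(quasi-extinct) %.4g\n",
    x$scenario$name, x$n_trajectories, x$horizon, x$mean_n, x$var_n,
    x$var_growth, x$p_extinct, x$p_quasi_extinct))
  invisible(x)
}

#' Expected one-year growth rate as a function of ROS, density and age
#' structure
#'
#' Deterministic one-year projections across a ROS grid for each
#' combination of initial density and prime-aged proportion, at fixed
#' winter length. Reports the ensemble mean and 2.5/97.5 percentiles of
#' `log(N1/N0)` per grid point.
#'
#' @param models list of fitted models.
#' @param densities initial total population sizes.
#' @param prime_fractions initial prime-aged (3-8) proportions.
#' @param ros_grid ROS values to scan (log scale).
#' @param winter_length fixed winter length (days).
#' @return data.frame `density`, `prime_fraction`, `ros`, `growth_mean`,
#'   `growth_lo`, `growth_hi`.
#' @export
growth_vs_ros_surface <- function(models, densities = c(1200, 1700),
                                  prime_fractions = c(0.28, 0.51),
                                  ros_grid = seq(0, 4.2, length.out = 22),
                                  winter_length = 210) {
  combos <- expand.grid(density = densities,
                        prime_fraction = prime_fractions,
                        ros = ros_grid)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(j) {
    cb <- combos[j, ]
    st0 <- build_initial_state(cb$density, cb$prime_fraction)
    g <- vapply(models, function(m) {
      pr <- project_population(m, st0, ros = cb$ros,
                               winter_length = winter_length,
                               mode = "deterministic")
      tot <- attr(pr, "total")
      log(tot[2] / tot[1])
    }, 0)
    data.frame(cb, growth_mean = mean(g),
               growth_lo = stats::quantile(g, 0.025),
               growth_hi = stats::quantile(g, 0.975), row.names = NULL)
  }))
  out[order(out$density, out$prime_fraction, out$ros), ]
}

#' Perturbation-timing experiment: two extreme winters at increasing lag
#'
#' Deterministic projections where ROS is held at its baseline (mean
#' observed) value except for a first extreme winter at t = 0 and a second
#' at t = `lag`; the sequences `"none"` (no second event) and
#' `"consecutive"` (extreme every winter from t = 0 on) are included. For
#' each sequence the expected growth rate in the second-event year is
#' summarised over the model ensemble, together with mean trajectories.
#'
#' @param models list of fitted models.
#' @param initial_state length-14 age vector (default: N = 1700 with 28%
#'   prime-aged, the pre-crash population state).
#' @param lags integer lags for the second event.
#' @param extreme_ros extreme ROS value (log scale).
#' @param baseline_ros baseline ROS value (mean of the study period).
#' @param winter_length fixed winter length (days).
#' @param horizon projection length in years.
#' @return list with `growth_at_second_event` (data.frame `lag`, `mean`,
#'   `lo`, `hi`), `first_event_growth` (ensemble mean), and `trajectories`
#'   (data.frame `lag`, `year`, `n_mean`, `n_lo`, `n_hi`).
#' @export
perturbation_timing <- function(models,
                                initial_state = build_initial_state(1700, 0.28),
                                lags = 1:7, extreme_ros = 4.2,
                                baseline_ros = 1.5, winter_length = 210,
                                horizon = 20) {
  seq_for <- function(lag) {
    ros <- rep(baseline_ros, horizon)
    ros[1] <- extreme_ros              # first event at t = 0
    if (identical(lag, "consecutive")) {
      ros[] <- extreme_ros
    } else if (!identical(lag, "none")) {
      ros[1 + as.integer(lag)] <- extreme_ros
    }
    ros
  }
  all_lags <- c(as.list(lags), list("none", "consecutive"))
  growth_rows <- list()
  traj_rows <- list()
  first_growth <- NULL
  for (lag in all_lags) {
    ros <- seq_for(lag)
    tots <- vapply(models, function(m) {
      pr <- project_population(m, initial_state, ros, winter_length,
                               mode = "deterministic")
      attr(pr, "total")
    }, numeric(horizon + 1L))
    lab <- as.character(lag)
    traj_rows[[lab]] <- data.frame(
      lag = lab, year = 0:horizon,
      n_mean = rowMeans(tots),
      n_lo = apply(tots, 1, stats::quantile, 0.025),
      n_hi = apply(tots, 1, stats::quantile, 0.975), row.names = NULL)
    if (is.null(first_growth))
      first_growth <- mean(log(tots[2, ] / tots[1, ]))
    if (!lab %in% c("none", "consecutive")) {
      i2 <- as.integer(lag) + 1L  # state index of the second-event year
      g2 <- log(tots[i2 + 1L, ] / tots[i2, ])
      growth_rows[[lab]] <- data.frame(
        lag = as.integer(lag), mean = mean(g2),
        lo = stats::quantile(g2, 0.025), hi = stats::quantile(g2, 0.975),
        row.names = NULL)
    }
  }
  list(growth_at_second_event = do.call(rbind, growth_rows),
       first_event_growth = first_growth,
       trajectories = do.call(rbind, traj_rows))
}

#' Contrast arithmetic over scenario summaries
#'
#' Pairwise contrasts between scenario summaries: percent reduction in mean
#' population size (rounded to the nearest percent) and ratios of
#' extinction and quasi-extinction probabilities. A zero denominator yields
#' `Inf` with a flag.
#'
#' @param table data.frame with columns `scenario`, `mean_n`, `p_extinct`,
#'   `p_quasi_extinct` (e.g. [svalbard_scenario_reference()] or rows built
#'   from [run_scenario()] results).
#' @param pairs optional 2-column character matrix of (from, to) scenario
#'   pairs; default: all ordered pairs.
#' @return data.frame `from`, `to`, `mean_n_reduction_pct`,
#'   `extinction_ratio`, `quasi_extinction_ratio`, `divide_by_zero`.
#' @examples
#' ref <- svalbard_scenario_reference()
#' summarize_contrasts(ref, rbind(c("medium", "very_high")))
#' @export
summarize_contrasts <- function(table, pairs = NULL) {
  stopifnot(nrow(table) >= 2)
  if (is.null(pairs)) {
    g <- expand.grid(from = table$scenario, to = table$scenario,
                     stringsAsFactors = FALSE)
    pairs <- as.matrix(g[g$from != g$to, ])
  }
  row_of <- function(s) {
    i <- match(s, table$scenario)
    if (is.na(i)) stop("unknown scenario: ", s)
    table[i, ]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    a <- row_of(pairs[j, 1]); b <- row_of(pairs[j, 2])
    ratio <- function(x, y) if (y == 0) Inf else x / y
    data.frame(from = a$scenario, to = b$scenario,
               mean_n_reduction_pct =
                 round(100 * (a$mean_n - b$mean_n) / a$mean_n),
               extinction_ratio = ratio(a$p_extinct, b$p_extinct),
               quasi_extinction_ratio =
                 ratio(a$p_quasi_extinct, b$p_quasi_extinct),
               divide_by_zero = (b$p_extinct == 0 || b$p_quasi_extinct == 0),
               row.names = NULL)
  }))
  out
}
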