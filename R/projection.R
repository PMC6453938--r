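N_AGES <- 14L  # single ages 0..13

# survival class (1..6) and fecundity class (1..5, NA for calves) per age
SURV_CLASS_OF_AGE <- c(1L, 2L, 3L, rep(4L, 6), rep(5L, 3), 6L, 6L)
FEC_CLASS_OF_AGE  <- c(NA, 1L, 2L, rep(3L, 6), rep(4L, 3), 5L, 5L)

#' Expand age-class rates to single-age rates
#'
#' Ages 0, 1, 2 take their own class rates; ages 3-8 share one class, ages
#' 9-11 another, and ages 12-13 the terminal class. Fecundity is undefined
#' for calves (age 0): the fecundity slot for age 0 is `NA`.
#'
#' @param rates list with `survival` (6 values) and `fecundity` (5 values),
#'   e.g. the output of [predict.vrm()].
#' @return list with `survival` and `fecundity`, each a length-14 vector
#'   indexed by age 0..13.
#' @export
expand_class_rates <- function(rates) {
  stopifnot(length(rates$survival) == 6L, length(rates$fecundity) == 5L)
  s <- unname(rates$survival)[SURV_CLASS_OF_AGE]
  f <- ifelse(is.na(FEC_CLASS_OF_AGE), NA_real_,
              unname(rates$fecundity)[FEC_CLASS_OF_AGE])
  names(s) <- names(f) <- 0:13
  list(survival = s, fecundity = f)
}

#' One-year update of the age-structured female population
#'
#' Removals (hunting `H` and culling `C`) are taken first; survivors of age
#' j move to age j + 1 (survivors of the terminal age 13 exit the
#' population). Calves are then produced by the surviving females aged 2-13
#' at t + 1, each mother's age-class fecundity evaluated at year-t
#' conditions, and a balanced sex ratio retains the female half. In
#' stochastic mode every transition is a binomial draw (demographic
#' stochasticity); in deterministic mode each binomial is replaced by its
#' expectation and the state is real-valued.
#'
#' @param state length-14 vector of female counts by single age 0..13.
#' @param s_age,f_age per-age survival and fecundity (see
#'   [expand_class_rates()]); `f_age[1]` (age 0) is ignored.
#' @param removals optional list or data.frame with per-age `hunted` and
#'   `culled` (length 14); default none.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return length-14 state vector at t + 1.
#' @export
step_population <- function(state, s_age, f_age, removals = NULL,
                            mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(length(state) == N_AGES, length(s_age) == N_AGES,
            length(f_age) == N_AGES, all(state >= 0),
            all(s_age >= 0 & s_age <= 1))
  h <- if (is.null(removals)) numeric(N_AGES) else removals$hunted
  cc <- if (is.null(removals)) numeric(N_AGES) else removals$culled
  avail <- state - h - cc
  if (any(avail < 0)) stop("removals exceed population")

  nxt <- numeric(N_AGES)
  if (mode == "stochastic") {
    surv <- stats::rbinom(N_AGES - 1L, size = round(avail[1:13]),
                          prob = s_age[1:13])
  } else {
    surv <- avail[1:13] * s_age[1:13]
  }
  nxt[2:14] <- surv  # survivors of age j fill age j+1; age-13 survivors exit

  mothers <- nxt[3:14]          # females aged 2..13 at t+1
  f_moth <- f_age[3:14]         # their age-specific fecundity (year-t rates)
  if (mode == "stochastic") {
    calves <- sum(stats::rbinom(length(mothers), size = mothers,
                                prob = f_moth))
    nxt[1] <- stats::rbinom(1L, size = calves, prob = 0.5)
  } else {
    nxt[1] <- 0.5 * sum(mothers * f_moth)
  }
  names(nxt) <- 0:13
  nxt
}

#' Multi-year projection with a fitted vital-rate model
#'
#' Iterates [step_population()] from an initial age vector, predicting each
#' year's vital rates from the model at the supplied ROS and winter-length
#' sequences. The post-hunt population size driving density dependence is
#' the current total after removals; the year-trend covariate is held fixed
#' at `year` (extrapolating a fitted linear trend over a century is not
#' defensible, so projections freeze it at the last training year by
#' default).
#'
#' @param model a fitted [fit_vital_rates()] model.
#' @param initial_state length-14 age vector (see [build_initial_state()]).
#' @param ros,winter_length covariate sequences, one value per projected
#'   year (recycled if scalar).
#' @param deviates optional `n_years x 11` matrix of environmental deviates
#'   (rows applied per year, logit scale).
#' @param year fixed value of the year-trend covariate (default: last
#'   training year).
#' @param removals optional list of per-year removal rows (each with
#'   `hunted`, `culled` length-14 vectors).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return matrix `(n_years + 1) x 14` of states, first row the initial
#'   state; attribute `"total"` holds the total-N series.
#' @export
project_population <- function(model, initial_state, ros, winter_length,
                               deviates = NULL, year = NULL,
                               removals = NULL,
                               mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  n_years <- max(length(ros), length(winter_length))
  ros <- rep_len(ros, n_years)
  winter_length <- rep_len(winter_length, n_years)
  year <- year %||% max(model$years)
  states <- matrix(0, n_years + 1L, N_AGES, dimnames = list(NULL, 0:13))
  states[1, ] <- initial_state
  st <- initial_state
  for (t in seq_len(n_years)) {
    rem <- if (is.null(removals)) NULL else removals[[t]]
    h <- if (is.null(rem)) 0 else sum(rem$hunted) + sum(rem$culled)
    n_post <- sum(st) - h
    dev <- if (is.null(deviates)) NULL else deviates[t, ]
    rates <- predict(model, ros = ros[t], winter_length = winter_length[t],
                     n_posthunt = n_post, year = year, deviate = dev)
    ar <- expand_class_rates(rates)
    st <- step_population(st, ar$survival, ar$fecundity, rem, mode = mode)
    states[t + 1L, ] <- st
    if (sum(st) == 0) {  # extinct: remaining years stay at zero
      break
    }
  }
  structure(states, total = rowSums(states))
}

#' One-step-ahead reconstruction of past population sizes
#'
#' For every observed transition t to t + 1, predicts the population at
#' t + 1 from the OBSERVED age vector at t (never from the model's own
#' previous prediction, so errors do not compound), using expected vital
#' rates at the observed covariates of year t. Returns predicted and
#' observed totals and log growth rates, and their Pearson correlation as
#' a predictive-power diagnostic.
#'
#' @param observed data.frame with columns `year`, `age` (0..13), `count`.
#' @param covariates data.frame `winter`, `ros`, `winter_length`.
#' @param model a fitted [fit_vital_rates()] model.
#' @param removals optional data.frame `year`, `age`, `hunted`, `culled`.
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @return data.frame `year`, `n_pred`, `n_obs`, `growth_pred`,
#'   `growth_obs`; attribute `"correlation"` is the Pearson correlation of
#'   the growth-rate series.
#' @export
reconstruct <- function(observed, covariates, model, removals = NULL,
                        mode = "deterministic") {
  years <- sort(unique(observed$year))
  if (!identical(years, seq(min(years), max(years))))
    stop("missing year in observed age structure")
  state_of <- function(y) {
    o <- observed[observed$year == y, ]
    st <- numeric(N_AGES)
    st[o$age + 1L] <- o$count
    st
  }
  rem_of <- function(y) {
    if (is.null(removals)) return(NULL)
    r <- removals[removals$year == y, ]
    h <- numeric(N_AGES); cc <- numeric(N_AGES)
    h[r$age + 1L] <- r$hunted; cc[r$age + 1L] <- r$culled
    list(hunted = h, culled = cc)
  }
  out <- data.frame(year = years[-1], n_pred = NA_real_, n_obs = NA_real_,
                    growth_pred = NA_real_, growth_obs = NA_real_)
  for (i in seq_len(length(years) - 1L)) {
    t0 <- years[i]
    st <- state_of(t0)
    rem <- rem_of(t0)
    cv <- covariates[covariates$winter == t0, ]
    if (nrow(cv) != 1L) stop("covariates missing for year ", t0)
    h <- if (is.null(rem)) 0 else sum(rem$hunted) + sum(rem$culled)
    rates <- predict(model, ros = cv$ros, winter_length = cv$winter_length,
                     n_posthunt = sum(st) - h, year = t0)
    ar <- expand_class_rates(rates)
    nxt <- step_population(st, ar$survival, ar$fecundity, rem, mode = mode)
    n_obs_t1 <- sum(state_of(years[i + 1L]))
    out$n_pred[i] <- sum(nxt)
    out$n_obs[i] <- n_obs_t1
    out$growth_pred[i] <- log(sum(nxt) / sum(st))
    out$growth_obs[i] <- log(n_obs_t1 / sum(st))
  }
  attr(out, "correlation") <- stats::cor(out$growth_pred, out$growth_obs)
  out
}

#' Proportion of prime-aged females (ages 3-8)
#'
#' @param state length-14 age vector.
#' @return fraction in \[0, 1\].
#' @export
prime_aged_proportion <- function(state) {
  stopifnot(length(state) == N_AGES)
  tot <- sum(state)
  if (tot <= 0) stop("empty population")
  sum(state[4:9]) / tot
}

distribute_exact <- function(n, k) {
  base <- floor(n / k)
  rem <- round(n - base * k)
  base + c(rep(1, rem), rep(0, k - rem))
}

#' Build an initial age vector from a total size and prime-aged fraction
#'
#' The prime-aged mass (`round(total_n * prime_fraction)`) is spread
#' uniformly over ages 3-8; the remainder uniformly over the other ages.
#' Integer rounding is corrected so the entries sum to `total_n` exactly.
#'
#' @param total_n total female population size.
#' @param prime_fraction fraction in ages 3-8 (in \[0, 1\]).
#' @return length-14 integer age vector summing to `total_n`.
#' @examples
#' st <- build_initial_state(1700, 0.28)
#' sum(st); prime_aged_proportion(st)
#' @export
build_initial_state <- function(total_n, prime_fraction) {
  stopifnot(prime_fraction >= 0, prime_fraction <= 1, total_n >= 0)
  prime_n <- round(total_n * prime_fraction)
  other_n <- total_n - prime_n
  st <- numeric(N_AGES)
  st[4:9] <- distribute_exact(prime_n, 6L)
  st[c(1:3, 10:14)] <- distribute_exact(other_n, 8L)
  names(st) <- 0:13
  st
}
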