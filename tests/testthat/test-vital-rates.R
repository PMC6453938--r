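test_that("the density-dependent ROS transform evaluates as specified", {
  expect_equal(ros_prime(2, 1234, 0), 2)        # k = 0: identity
  expect_equal(ros_prime(2, 1000, -0.001), 2 * exp(-1))
  expect_equal(ros_prime(0, 5000, 0.008), 0)    # zero ROS stays zero
  # overflow guard: extreme k * N stays finite
  expect_true(is.finite(ros_prime(4.2, 1e6, 0.01)))
})

test_that("the ROS effect never changes sign across population sizes", {
  set.seed(4)
  k <- runif(1000, -0.01, 0.01)
  n <- runif(1000, 0, 5000)
  ros <- runif(1000, 0.01, 4.2)
  b <- -0.04  # any single-signed coefficient
  eff <- b * ros_prime(ros, n, k)
  expect_true(all(eff < 0))
  expect_true(all(-eff > 0))  # and with b > 0 strictly positive
})

test_that("a noise-free single-sample panel recovers the generating model", {
  gt <- ground_truth_preset()
  dat <- generate_posterior_panel(gt, n_samples = 1, years = 1994:2015,
                                  seed = 5, obs_noise_sd = 0,
                                  n_obs_noise_sd = 0)
  # zero observation noise: the panel equals the realised true rates
  s1 <- dat$panel[dat$panel$sample_id == 1 & dat$panel$rate_type == "S", ]
  expect_equal(s1$value[order(s1$year, s1$age_class)],
               as.vector(dat$true_rates$survival[
                 , order(as.integer(colnames(dat$true_rates$survival)))]),
               tolerance = 1e-12)

  fit <- fit_vital_rates(dat$panel, dat$covariates,
                         dat$n_posthunt[dat$n_posthunt$sample_id == 1, ])
  # k and the reference-class ROS' slope recovered from one clean sample
  expect_lt(abs(fit$survival$k - gt$model$survival$k),
            0.5 * gt$model$survival$k)
  expect_lt(fit$survival$fixef[["rosp"]], 0)
  expect_lt(fit$fecundity$fixef[["rosp"]], 0)
  # AIC at selected k beats both search-bound endpoints
  prof <- fit$survival$k_profile
  expect_lte(fit$survival$aic, prof$aic[1])
  expect_lte(fit$survival$aic, prof$aic[nrow(prof)])
})

test_that("fitting is deterministic for identical panels", {
  gt <- ground_truth_preset()
  dat <- generate_posterior_panel(gt, n_samples = 1, years = 1994:2015,
                                  seed = 6)
  np <- dat$n_posthunt[dat$n_posthunt$sample_id == 1, ]
  f1 <- fit_vital_rates(dat$panel, dat$covariates, np)
  f2 <- fit_vital_rates(dat$panel, dat$covariates, np)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sigma, f2$sigma)
})

test_that("sigma estimation matches a direct covariance computation", {
  # build a minimal vrm skeleton with known deviations
  set.seed(9)
  yrs <- 2000:2009
  mk <- function(nc) {
    res <- matrix(rnorm(nc * 10, 0, 0.2), nc, 10,
                  dimnames = list(seq_len(nc), yrs))
    ran <- setNames(rnorm(10, 0, 0.3), yrs)
    list(residuals = res, ranef_year = ran)
  }
  obj <- structure(list(survival = mk(6), fecundity = mk(5), years = yrs),
                   class = "vrm")
  sig <- estimate_sigma(obj)
  dev <- rbind(obj$survival$residuals +
                 rep(obj$survival$ranef_year, each = 6),
               obj$fecundity$residuals +
                 rep(obj$fecundity$ranef_year, each = 5))
  expect_equal(unname(sig), unname(cov(t(dev))), tolerance = 1e-10)
  expect_true(isSymmetric(sig))
  expect_gte(min(eigen(sig, only.values = TRUE)$values), -1e-10)
})

test_that("environmental deviates have the requested covariance", {
  expect_equal(sample_env_deviates(diag(0, 11), 5),
               matrix(0, 5, 11), ignore_attr = TRUE)
  d <- sample_env_deviates(diag(11), 1e5, seed = 10)
  expect_equal(unname(apply(d, 2, var)), rep(1, 11),
               tolerance = 3 * sqrt(2 / 1e5) * 3)
  a <- sample_env_deviates(diag(11), 4, seed = 2)
  b <- sample_env_deviates(diag(11), 4, seed = 2)
  expect_identical(a, b)
  bad <- diag(11); bad[1, 1] <- -1
  expect_error(sample_env_deviates(bad, 2), "positive semi-definite")
})

test_that("predictions respect (0,1), monotonicity and density amplification", {
  gt <- ground_truth_preset()
  m <- gt$model
  ros_grid <- seq(0, 4.2, by = 0.6)
  p <- lapply(ros_grid, function(r)
    predict(m, ros = r, winter_length = 210, n_posthunt = 1500,
            year = 2005))
  s_calf <- vapply(p, function(x) x$survival[["0"]], 0)
  expect_true(all(diff(s_calf) < 0))  # negative ROS' slope: decreasing
  all_rates <- unlist(p)
  expect_true(all(all_rates > 0 & all_rates < 1))

  # k > 0 with negative slope: same ROS change moves the logit more at
  # high density than at low density
  dlogit <- function(n) {
    p0 <- predict(m, 0, 210, n, 2005)$survival[["0"]]
    p1 <- predict(m, 4.2, 210, n, 2005)$survival[["0"]]
    abs(qlogis(p1) - qlogis(p0))
  }
  expect_lt(dlogit(500), dlogit(2000))

  # an explicit deviate shifts the logit additively
  dv <- c(rep(0.5, 6), rep(-0.5, 5))
  pd <- predict(m, 1, 210, 1500, 2005, deviate = dv)
  p0 <- predict(m, 1, 210, 1500, 2005)
  expect_equal(qlogis(pd$survival) - qlogis(p0$survival), rep(0.5, 6),
               ignore_attr = TRUE)
})

test_that("vrm methods print, summarise and simulate coherently", {
  gt <- ground_truth_preset()
  dat <- generate_posterior_panel(gt, n_samples = 1, years = 1994:2015,
                                  seed = 13)
  fit <- fit_vital_rates(dat$panel, dat$covariates,
                         dat$n_posthunt[dat$n_posthunt$sample_id == 1, ])
  expect_output(print(fit), "k =")
  expect_output(print(summary(fit)), "AIC")
  cf <- coef(fit)
  expect_named(cf, c("survival", "fecundity", "k"))
  d <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(d), c(3, 11))
})

test_that("fitted models survive a JSON round-trip", {
  skip_if_not_installed("jsonlite")
  gt <- ground_truth_preset()
  m <- gt$model
  f <- tempfile(fileext = ".json")
  write_vrm_json(m, f)
  m2 <- read_vrm_json(f)
  p1 <- predict(m, ros = 2.5, winter_length = 220, n_posthunt = 1400,
                year = 2010)
  p2 <- predict(m2, ros = 2.5, winter_length = 220, n_posthunt = 1400,
                year = 2010)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(m2$sigma, m$sigma, tolerance = 1e-12)
  unlink(f)
})
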