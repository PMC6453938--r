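test_that("class rates expand to block-constant age profiles", {
  r <- list(survival = rep(0.5, 6), fecundity = rep(0.5, 5))
  e <- expand_class_rates(r)
  expect_equal(unname(e$survival), rep(0.5, 14))
  expect_true(is.na(e$fecundity[["0"]]))

  r <- list(survival = c(.1, .2, .3, .4, .5, .6),
            fecundity = c(.1, .2, .3, .4, .5))
  e <- expand_class_rates(r)
  expect_equal(unname(e$survival),
               c(.1, .2, .3, rep(.4, 6), rep(.5, 3), .6, .6))
  expect_equal(unname(e$fecundity[-1]),
               c(.1, .2, rep(.3, 6), rep(.4, 3), .5, .5))
})

test_that("degenerate steps behave as permutation and absorption", {
  st <- c(5, rep(10, 13))
  # perfect survival, no births: pure age shift, only age-13 exits
  nxt <- step_population(st, rep(1, 14), rep(0, 14), mode = "deterministic")
  expect_equal(unname(nxt), c(0, 5, rep(10, 12)))
  expect_equal(sum(nxt), sum(st) - 10)
  # zero survival: no survivors, hence no mothers, hence no calves
  nxt <- step_population(st, rep(0, 14), rep(0.9, 14), mode = "stochastic")
  expect_equal(unname(nxt), rep(0, 14))
})

test_that("the deterministic step reproduces the hand-computed expectation", {
  # N = 10 at each age 2..13, S = 0.8, F = 0.5, no removals:
  # survivors move ages 3..13 at 8 each; mothers at t+1 are ages 2..13
  # (age 2 is empty: no age-1 females at t), so 11 x 8 = 88 mothers,
  # 44 expected calves, 22 female
  st <- c(0, 0, rep(10, 12))
  nxt <- step_population(st, rep(0.8, 14), rep(0.5, 14),
                         mode = "deterministic")
  expect_equal(unname(nxt), c(22, 0, 0, rep(8, 11)))
})

test_that("stochastic steps are integer-valued and seed-reproducible", {
  st <- c(50, rep(30, 13))
  set.seed(8)
  a <- step_population(st, rep(0.8, 14), rep(0.5, 14))
  set.seed(8)
  b <- step_population(st, rep(0.8, 14), rep(0.5, 14))
  expect_identical(a, b)
  expect_true(all(a == round(a)))
  expect_true(all(a >= 0))
})

test_that("removals are honoured and over-removal is an error", {
  st <- c(0, 0, rep(10, 12))
  rem <- list(hunted = c(0, 0, 5, rep(0, 11)), culled = rep(0, 14))
  nxt <- step_population(st, rep(1, 14), rep(0, 14), removals = rem,
                         mode = "deterministic")
  expect_equal(unname(nxt[4]), 5)  # age 2 had 10, 5 removed, survivors 5
  rem$hunted[3] <- 11
  expect_error(step_population(st, rep(1, 14), rep(0, 14), removals = rem),
               "removals exceed")
})

test_that("prime-aged proportion and initial-state builder are consistent", {
  st <- numeric(14); st[4:9] <- 7
  expect_equal(prime_aged_proportion(st), 1)
  expect_equal(prime_aged_proportion(rep(1, 14)), 6 / 14)
  expect_error(prime_aged_proportion(numeric(14)), "empty")

  st <- build_initial_state(1700, 0.28)
  expect_equal(sum(st), 1700)
  expect_equal(sum(st[4:9]), round(1700 * 0.28))
  expect_equal(prime_aged_proportion(st), 0.28, tolerance = 0.001)
  expect_true(all(st == round(st)))

  expect_equal(sum(build_initial_state(1200, 1)[4:9]), 1200)
  expect_equal(sum(build_initial_state(1200, 0)[4:9]), 0)
})

test_that("reconstruction is self-consistent under the generating model", {
  gt <- ground_truth_preset()
  truth <- gt$model
  # reconstruction evaluates the year covariate per step while the forward
  # projection freezes it; silence the trend so the two paths agree exactly
  truth$survival$b_year <- 0
  truth$fecundity$b_year <- 0
  set.seed(31)
  cov <- winter_covariates(generate_weather(gt, 1994:2015), 1994, 2015)
  # noise-free observations: deterministic projection of the truth itself
  st0 <- build_initial_state(1200, 0.4)
  yrs <- 1994:2015
  pr <- project_population(truth, st0,
                           ros = cov$ros[match(1994:2014, cov$winter)],
                           winter_length =
                             cov$winter_length[match(1994:2014, cov$winter)],
                           year = 2004, mode = "deterministic")
  obs2 <- data.frame(year = rep(yrs, each = 14), age = rep(0:13, 22),
                     count = as.vector(t(unclass(pr))))
  rec <- reconstruct(obs2, cov, truth, mode = "deterministic")
  expect_gt(attr(rec, "correlation"), 0.999)
  expect_equal(rec$n_pred, rec$n_obs, tolerance = 1e-8)

  # negative control: permuted covariate years destroy the correlation
  cov_perm <- cov
  set.seed(12)
  cov_perm$ros <- sample(cov_perm$ros)
  rec_perm <- reconstruct(obs2, cov_perm, truth, mode = "deterministic")
  expect_lt(attr(rec_perm, "correlation"), 0.5)
})

test_that("projection with extinction stays extinct and records totals", {
  gt <- ground_truth_preset()
  st <- build_initial_state(4, 0.5)
  set.seed(2)
  pr <- project_population(gt$model, st, ros = rep(4.2, 30),
                           winter_length = 210, mode = "stochastic")
  tot <- attr(pr, "total")
  if (any(tot == 0)) {
    first0 <- which(tot == 0)[1]
    expect_true(all(tot[first0:length(tot)] == 0))
  }
  expect_equal(length(tot), 31)
})
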