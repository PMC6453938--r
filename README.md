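# rosdemog

Stochastic demography of High-Arctic ungulates under rain-on-snow (ROS)
regimes.

Rain falling on Arctic winter snow refreezes into ground ice that locks
pastures away from grazing reindeer. Single icing winters cause dramatic
die-offs, so more frequent ROS winters under climate warming look like a
straightforward threat. Whether they actually destabilise a population
depends on how the icing damage interacts with density dependence and age
structure: crashes hit calves and old females at high density, and leave
behind a small, prime-aged, resilient population. `rosdemog` provides the
modelling chain needed to study that interaction quantitatively, for
population ecologists working with age-structured time series and
posterior ensembles from integrated population models (IPMs).

## What the package computes

* **Winter covariates** from daily weather: the ROS index
  `log(1 + Σ precip on days ≥ 1 °C, Nov–Apr)` and winter length from
  sustained crossings of a 10-day running temperature mean
  (`compute_ros()`, `compute_winter_length()`, `winter_covariates()`).
* **Density-dependent vital-rate models** per posterior sample
  (`fit_vital_rates()`): for survival *S* and fecundity *F* of age class
  *i* in year *t*, on the logit scale,

  ```
  logit(rate[i,t]) = a[i] + bN·Ñ[t] + byr·t + (bR + d[i])·ROS'[t]
                     + bW·winterlength[t] + u[t] + ε[i,t]
  ROS'[t] = ROS[t] · exp(k · N_posthunt[t])
  ```

  with a random year intercept `u[t]`, fitted by maximum likelihood
  (`lme4`), and the interaction shape `k` chosen by AIC minimisation. The
  exponential form keeps the ROS effect single-signed across all
  densities; `k > 0` means icing bites hardest at high density. The
  11×11 covariance Σ of annual class-rate deviations (random year effect
  + residual) drives environmental stochasticity downstream.
* **Age-structured projection** at single ages 0–13 with binomial
  demographic stochasticity, harvest/cull removals and a balanced sex
  ratio (`step_population()`, `project_population()`), one-step-ahead
  **reconstruction** of an observed period (`reconstruct()`).
* **ROS-frequency scenarios** by beta inverse-transform sampling over the
  observed ROS pool — `U ~ Beta(α1, α2)`, `X = Q(U)` — from very low
  (1, 4) to very high (4, 1) extreme-winter frequency (`sample_ros()`),
  and 100-year stochastic simulations with extinction and
  quasi-extinction summaries (`run_scenario()`).
* **Experiments**: growth-rate regression with a ROS×density interaction
  (`fit_growth_regression()`), growth-vs-ROS response surfaces by density
  and age structure (`growth_vs_ros_surface()`), and perturbation-timing
  simulations of paired extreme winters (`perturbation_timing()`).
* **Synthetic ground truth** (`ground_truth_preset()`,
  `generate_weather()`, `generate_posterior_panel()`): a fully specified
  generating model emulating an IPM posterior ensemble, so the whole
  pipeline is testable without field data.

## Worked example

```r
library(rosdemog)

gt <- ground_truth_preset()
set.seed(1)
dat <- generate_posterior_panel(gt, n_samples = 1, years = 1994:2015)

fit <- fit_vital_rates(dat$panel, dat$covariates,
                       dat$n_posthunt[dat$n_posthunt$sample_id == 1, ])
print(fit)
#> Density-dependent vital-rate model (logit-linear mixed, ML)
#>   years: 1994-2014 (21), N scaling: mean 1350, sd 229
#>   survival : k = +0.00194 (AIC 104.9)
#>   fecundity: k = +0.00187 (AIC 114.2)
#>   ROS' slope (ref class): S -0.050, F -0.045
```

The fitted `k` of about +0.002 (the generating value) with negative ROS′
slopes says that icing winters depress survival and fecundity, and do so
increasingly at high density. The model reconstructs the simulated
observation period almost perfectly:

```r
rec <- reconstruct(dat$age_structure, dat$covariates, fit,
                   removals = dat$removals)
attr(rec, "correlation")
#> growth-rate correlation: 0.976
```

Hundred-year stochastic projections under the historical ROS-frequency
regime versus a much icier future:

```r
pool <- winter_covariates(generate_weather(gt, 1962:2014), 1962, 2014)$ros
wl <- summarize_winter_length(dat$covariates)
init <- dat$age_structure[dat$age_structure$year == 2015, ]
init <- init$count[order(init$age)]
run_scenario(list(fit), init, ros_scenario("medium"), pool,
             wl[["mean"]], wl[["sd"]], horizon = 100,
             reps_per_model = 50, seed = 2)
#> Scenario 'medium' (50 trajectories x 100 years)
#>   mean N 1397, var N 78497, var growth 0.0913
#>   P(extinct) 0, P(quasi-extinct) 0
run_scenario(list(fit), init, ros_scenario("very_high"), pool, ...)
#> Scenario 'very_high' (50 trajectories x 100 years)
#>   mean N 1305, var N 22123, var growth 0.0364
#>   P(extinct) 0, P(quasi-extinct) 0
```

Very frequent extreme winters cost only ~7% of mean population size here,
but cut the variance of population size by a factor of ~3.5 and the
growth-rate variance by ~2.5: frequent perturbations keep the population
in a low-density, prime-aged state that icing can barely touch. That is
the stabilisation mechanism the package exists to analyse.

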