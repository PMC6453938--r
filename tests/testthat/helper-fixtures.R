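# shared fixtures, built in code

# two-regime daily series: warm until 30 Sep, cold through 31 May, warm after
step_weather <- function(year = 1996, cold = -5, warm = 5) {
  dates <- seq(as.Date(sprintf("%d-08-01", year - 1)),
               as.Date(sprintf("%d-07-31", year)), by = "day")
  cold_start <- as.Date(sprintf("%d-10-01", year - 1))
  cold_end <- as.Date(sprintf("%d-05-31", year))
  data.frame(date = dates,
             mean_temp = ifelse(dates >= cold_start & dates <= cold_end,
                                cold, warm),
             precip = 0)
}

# cold winter series with a chosen set of warm rain days inside Nov-Apr
ros_weather <- function(year = 1996, warm_days = NULL, warm_temp = 2,
                        warm_precip = 10) {
  w <- step_weather(year)
  if (!is.null(warm_days)) {
    i <- match(as.Date(warm_days), w$date)
    w$mean_temp[i] <- warm_temp
    w$precip[i] <- warm_precip
  }
  w
}

# lazily fitted synthetic posterior ensemble, shared across test files
.ensemble_cache <- new.env(parent = emptyenv())

synthetic_ensemble <- function(n_samples = 200, seed = 42) {
  key <- sprintf("ens_%d_%d", n_samples, seed)
  if (!is.null(.ensemble_cache[[key]])) return(.ensemble_cache[[key]])
  gt <- ground_truth_preset()
  set.seed(seed)
  pool_cov <- winter_covariates(generate_weather(gt, 1962:2014), 1962, 2014)
  dat <- generate_posterior_panel(gt, n_samples = n_samples,
                                  years = 1994:2015)
  fits <- lapply(seq_len(n_samples), function(s) {
    fit_vital_rates(dat$panel[dat$panel$sample_id == s, ],
                    dat$covariates,
                    dat$n_posthunt[dat$n_posthunt$sample_id == s, ])
  })
  last <- dat$age_structure[dat$age_structure$year == 2015, ]
  out <- list(gt = gt, dat = dat, fits = fits,
              pool = pool_cov$ros,
              wl = summarize_winter_length(dat$covariates),
              init2014 = last$count[order(last$age)])
  .ensemble_cache[[key]] <- out
  out
}
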