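test_that("ROS index follows the warm-precipitation log formula", {
  # no day at or above the 1 C threshold -> log(1 + 0) = 0
  expect_identical(compute_ros(ros_weather(), 1996), 0)

  # a single warm rain day of 10 mm -> log(11)
  w <- ros_weather(warm_days = "1996-01-15", warm_precip = 10)
  expect_equal(compute_ros(w, 1996), log(11))

  # warm-day precipitation of exp(4.2) - 1 mm recovers the extreme value 4.2
  w <- ros_weather(warm_days = "1996-02-01", warm_precip = exp(4.2) - 1)
  expect_equal(compute_ros(w, 1996), 4.2)

  # the threshold is inclusive: a day at exactly 1 C counts
  w <- ros_weather(warm_days = "1996-03-01", warm_temp = 1, warm_precip = 5)
  expect_equal(compute_ros(w, 1996), log(6))

  # cold-day precipitation is irrelevant
  w <- ros_weather(warm_days = "1996-01-15", warm_precip = 10)
  w$precip[w$mean_temp < 1] <- 20
  expect_equal(compute_ros(w, 1996), log(11))
})

test_that("ROS is monotone in warm precipitation and order-invariant", {
  amounts <- c(1, 5, 20, 50)
  ros <- vapply(amounts, function(a)
    compute_ros(ros_weather(warm_days = "1996-01-15", warm_precip = a),
                1996), 0)
  expect_true(all(diff(ros) > 0))

  w <- ros_weather(warm_days = c("1996-01-15", "1996-02-10"))
  shuffled <- w[sample(nrow(w)), ]
  expect_equal(compute_ros(shuffled, 1996), compute_ros(w, 1996))
  expect_equal(compute_winter_length(shuffled, 1996),
               compute_winter_length(w, 1996))
})

test_that("ROS flags empty and gappy winters", {
  w <- ros_weather()
  expect_error(compute_ros(w[w$date < as.Date("1995-11-01"), ], 1996),
               "no winter data")
  # drop 30 of ~181 window days (> 10%) -> warning, computation proceeds
  win <- w$date >= as.Date("1995-11-01") & w$date <= as.Date("1996-04-30")
  gappy <- w[-which(win)[1:30], ]
  expect_warning(r <- compute_ros(gappy, 1996), "missing")
  expect_identical(r, 0)
})

test_that("winter length follows the sustained 10-day running-mean rule", {
  # two-regime series, cold 1 Oct-31 May: trailing-mean crossings are
  # offset symmetrically at onset and end, so length = cold-block length
  # (243 days for a non-leap winter)
  w <- step_weather(1995)
  expect_equal(compute_winter_length(w, 1995), 243)

  # a 5-day warm spike in January breaks neither boundary criterion
  spike <- w
  i <- match(seq(as.Date("1995-01-10"), by = "day", length.out = 5), w$date)
  spike$mean_temp[i] <- 5
  expect_equal(compute_winter_length(spike, 1995), 243)

  # block-length identity holds for other symmetric cold blocks too
  w2 <- step_weather(1997)
  cold2 <- w2$date >= as.Date("1996-10-15") & w2$date <= as.Date("1997-05-10")
  w2$mean_temp <- ifelse(cold2, -5, 5)
  expect_equal(compute_winter_length(w2, 1997),
               as.numeric(as.Date("1997-05-11") - as.Date("1996-10-15")))

  # perpetual cold: no end of winter detectable
  frozen <- w
  frozen$mean_temp <- -5
  expect_error(compute_winter_length(frozen, 1996), "undetected")
})

test_that("winter-length summary gives sample mean and sd", {
  cov2 <- data.frame(winter = 1:2, winter_length = c(200, 220))
  s <- summarize_winter_length(cov2)
  expect_equal(unname(s["mean"]), 210)
  expect_equal(unname(s["sd"]), sd(c(200, 220)))

  cov3 <- data.frame(winter = 1:3, winter_length = rep(210, 3))
  expect_equal(unname(summarize_winter_length(cov3)["sd"]), 0)

  expect_error(summarize_winter_length(cov2[1, ]), "at least 2")

  # period filtering
  cov4 <- data.frame(winter = 1994:2014,
                     winter_length = c(rep(200, 10), rep(240, 11)))
  s <- summarize_winter_length(cov4, period = 1994:2003)
  expect_equal(unname(s["mean"]), 200)
})

test_that("weather CSV round-trips through the reader", {
  w <- ros_weather(warm_days = "1996-01-15")
  f <- tempfile(fileext = ".csv")
  write.csv(w, f, row.names = FALSE)
  r <- read_daily_weather(f)
  expect_equal(r$precip, w$precip)
  expect_s3_class(r$date, "Date")
  expect_equal(compute_ros(r, 1996), compute_ros(w, 1996))
  unlink(f)

  bad <- w; bad$precip[5] <- -1
  expect_error(as_daily_weather(bad), "negative precipitation")
})
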