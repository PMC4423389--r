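test_that("same-day replicates collapse to their daily mean", {
  d <- as.Date("2000-07-05")
  s <- temperature_series(c(d, d, d + 1), c(10, 12, 14))
  out <- dedupe_daily(s)
  expect_identical(out$dates, c(d, d + 1))
  expect_identical(out$temp_c, c(11, 14))
  unique_s <- temperature_series(c(d, d + 3), c(10, 12))
  expect_identical(dedupe_daily(unique_s)$temp_c, unique_s$temp_c)
  empty <- temperature_series(as.Date(character(0)), numeric(0))
  expect_length(dedupe_daily(empty)$dates, 0)
})

test_that("daily interpolation passes through observations and averages chords", {
  w <- jas_window()
  # endpoints only: linear ramp, mean = midpoint
  s <- temperature_series(c(w$start_date, w$end_date), c(10, 12))
  daily <- interpolate_daily(s, w)
  expect_equal(nrow(daily), 92)
  expect_equal(mean(daily$temp_c), 11.0)
  expect_equal(daily$temp_c[1], 10)
  expect_equal(daily$temp_c[92], 12)
  # constant series stays constant
  d <- seq(w$start_date - 10, w$end_date + 10, by = "7 days")
  s2 <- temperature_series(d, rep(15, length(d)))
  expect_equal(interpolate_daily(s2, w)$temp_c, rep(15, 92))
  # interpolant equals observations on observation dates
  s3 <- random_bracketing_series(42, w)
  daily3 <- interpolate_daily(s3, w)
  inwin <- s3$dates >= w$start_date & s3$dates <= w$end_date
  expect_equal(daily3$temp_c[match(s3$dates[inwin], daily3$date)],
               s3$temp_c[inwin])
  # truncated sampling signals extrapolation, not a crash
  s4 <- temperature_series(w$start_date + c(20, 40, 60), c(18, 20, 19))
  expect_error(interpolate_daily(s4, w),
               class = "laketherm_needs_extrapolation")
})

test_that("gap statistics use only in-window sequential samples", {
  w <- jas_window()
  s <- temperature_series(as.Date(c("2000-06-20", "2000-07-01", "2000-07-11",
                                    "2000-07-31", "2000-10-05")),
                          c(15, 16, 17, 18, 14))
  g <- gap_statistics(s, w)
  expect_equal(g$max_gap, 20)
  expect_equal(g$mean_gap, 15)
  dense <- temperature_series(seq(w$start_date, w$end_date, by = "day"),
                              rep(20, 92))
  gd <- gap_statistics(dense, w)
  expect_equal(gd$max_gap, 1)
  expect_equal(gd$mean_gap, 1)
  one <- temperature_series(as.Date("2000-08-01"), 20)
  go <- gap_statistics(one, w)
  expect_true(is.na(go$max_gap) && is.na(go$mean_gap))
})

test_that("pooled day-of-year parabola is the exact OLS quadratic", {
  d <- as.Date("1999-12-31") + c(180, 200, 220)
  p <- fit_seasonal_parabola(temperature_series(d, c(20, 22, 20)))
  expect_equal(p$a, -0.005, tolerance = 1e-12)
  expect_equal(p$b, 2, tolerance = 1e-12)
  expect_equal(p$c, -178, tolerance = 1e-10)
  expect_equal(p$r_squared, 1)
  # constant data give a flat parabola with R^2 defined as 1
  pc <- fit_seasonal_parabola(
    temperature_series(as.Date("2000-06-01") + c(0, 20, 40), rep(12, 3)))
  expect_equal(pc$a, 0)
  expect_equal(pc$b, 0)
  expect_equal(pc$c, 12)
  expect_equal(pc$r_squared, 1)
  expect_error(
    fit_seasonal_parabola(temperature_series(as.Date("2000-06-01") + c(0, 1),
                                             c(10, 11))),
    class = "laketherm_insufficient_data")
})

test_that("noisy parabola coefficients are recovered within error bands", {
  set.seed(7)
  doy <- sample(150:280, 200, replace = TRUE)
  a <- -0.004; b <- 1.7; cc <- -158
  d <- as.Date("1999-12-31") + doy
  y <- a * doy^2 + b * doy + cc + rnorm(200, 0, 0.5)
  p <- fit_seasonal_parabola(temperature_series(d, y, plausible_range = NULL))
  expect_lt(abs(p$a - a), 1.96 * p$se[["a"]])
  expect_lt(abs(p$b - b), 1.96 * p$se[["b"]])
  expect_lt(abs(p$c - cc), 1.96 * p$se[["c"]])
})

test_that("boundary extrapolation anchors the shifted parabola exactly", {
  w <- jas_window()
  pool_doy <- c(150, 170, 190, 210, 230, 250, 270)
  pool_d <- as.Date("1999-12-31") + pool_doy
  pool_t <- -0.005 * pool_doy^2 + 2 * pool_doy - 178
  parab <- fit_seasonal_parabola(temperature_series(pool_d, pool_t))
  # season starts late: first sample 2000-07-20, off the pooled curve
  obs_d <- as.Date(c("2000-07-20", "2000-08-15", "2000-10-02"))
  obs_t <- c(predict(parab, laketherm:::.doy(obs_d[1])) - 0.5, 21, 17)
  s <- temperature_series(obs_d, obs_t, site_id = "L1")
  ext <- extrapolate_boundary(s, w, parab)
  expect_identical(ext$sides, "start")
  # continuity: shifted curve meets the anchoring observation exactly
  expect_equal(ext$daily$temp_c[ext$daily$date == obs_d[1]], obs_t[1])
  head_d <- ext$daily$date < obs_d[1]
  shifted <- shift_parabola(parab, laketherm:::.doy(obs_d[1]), obs_t[1])
  expect_equal(ext$daily$temp_c[head_d],
               predict(shifted, laketherm:::.doy(ext$daily$date[head_d])))
  expect_identical(ext$log$side, "start")
  expect_equal(ext$log$c, shifted$c)
  # anchor on the pooled curve -> zero shift
  s0 <- temperature_series(
    as.Date("1999-12-31") + c(195, 230, 270),
    predict(parab, c(195, 230, 270)))
  ext0 <- extrapolate_boundary(s0, w, parab)
  expect_equal(ext0$log$c[1], parab$c)
})

test_that("seasonal mean combines interpolation and extrapolation correctly", {
  w <- jas_window()
  # full-coverage constant
  d <- seq(w$start_date - 5, w$end_date + 5, by = "10 days")
  m <- insitu_seasonal_mean(temperature_series(d, rep(15, length(d))), w)
  expect_equal(m$mean, 15)
  expect_identical(m$method, "interpolated")
  expect_null(m$log)
  # one observation, no parabola -> insufficient
  m1 <- insitu_seasonal_mean(temperature_series(as.Date("2000-08-01"), 20), w)
  expect_identical(m1$method, "insufficient_data")
  expect_true(is.na(m1$mean))
  # truncated start with parabola: mean equals explicit daily reconstruction
  pool_doy <- seq(120, 320, by = 10)
  parab <- fit_seasonal_parabola(temperature_series(
    as.Date("1999-12-31") + pool_doy,
    22 - 0.002 * (pool_doy - 210)^2))
  obs_d <- seq(as.Date("2000-07-25"), as.Date("2000-10-03"), by = "7 days")
  obs_t <- 21.5 - 0.002 * (laketherm:::.doy(obs_d) - 210)^2
  s <- temperature_series(obs_d, obs_t)
  m2 <- insitu_seasonal_mean(s, w, parabola = parab)
  expect_identical(m2$method, "interpolated+extrapolated_start")
  ext <- extrapolate_boundary(s, w, parab)
  expect_equal(m2$mean, mean(ext$daily$temp_c))
  expect_identical(m2$log$side, "start")
  # truncated both sides -> one log entry per side, independent shifts
  s3 <- temperature_series(obs_d[2:8], obs_t[2:8])
  m3 <- insitu_seasonal_mean(s3, w, parabola = parab)
  expect_identical(m3$method, "interpolated+extrapolated_both")
  expect_setequal(m3$log$side, c("start", "end"))
  # without a parabola the truncated season is insufficient
  m4 <- insitu_seasonal_mean(s3, w)
  expect_identical(m4$method, "insufficient_data")
})

test_that("seasonal means agree with an independent brute-force oracle", {
  w <- jas_window()
  for (seed in 1:20) {
    s <- random_bracketing_series(seed, w)
    m <- insitu_seasonal_mean(s, w)
    expect_equal(m$mean, brute_force_seasonal_mean(s$dates, s$temp_c, w),
                 tolerance = 1e-9)
  }
})

test_that("interpolation bias on a sampled quadratic follows a*h^2/6", {
  k <- 0.002; t0 <- as.numeric(as.Date("2000-08-05"))
  truth <- function(t) 23 - k * (t - t0)^2
  dates <- seq(as.Date("2000-06-01"), as.Date("2000-10-31"), by = "day")
  daily <- temperature_series(dates, truth(as.numeric(dates)))
  from <- as.Date("2000-07-01")
  h <- 10
  sub <- subsample(daily, h, from)
  bias <- interpolation_bias(sub, from, from + 90, truth)
  expect_equal(bias, -k * h^2 / 6, tolerance = 1e-9)
})
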