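# small helper: n clean 3x3 retrievals of a given temperature
make_retrievals <- function(dates, temp, sensor = "AATSR", zenith = 20,
                            spread = 0, skin = FALSE) {
  n <- length(dates)
  px <- matrix(rep(temp, each = 9), n, 9, byrow = TRUE)
  if (spread > 0) px <- px + rep_len(c(spread, -spread), 9)
  satellite_retrievals("L1", dates, sensor, rep_len(zenith, n), px,
                       skin = skin)
}

test_that("zenith screening keeps <= 45 degrees and discards above", {
  r <- satellite_retrievals("L1", as.Date("2000-07-01") + 0:2, "AVHRR",
                            c(44.9, 45.0, 45.1), c(14, 14, 14))
  kept <- zenith_filter(r)
  expect_equal(kept$zenith_deg, c(44.9, 45.0))
  nadir <- satellite_retrievals("L1", as.Date("2000-07-01") + 0:4, "AVHRR",
                                rep(0, 5), rep(14, 5))
  expect_equal(nrow(zenith_filter(nadir)), 5)
  expect_equal(nrow(zenith_filter(nadir[0, ])), 0)
})

test_that("homogeneity test drops 3x3 arrays with SD above 0.5 degC", {
  d <- as.Date("2000-07-01")
  uniform <- make_retrievals(d, 10)                       # SD 0
  expect_equal(nrow(homogeneity_filter(uniform)), 1)
  # eight pixels at 10, one at 12: sample SD = 2/3 > 0.5 -> drop
  px <- matrix(c(rep(10, 8), 12), 1, 9)
  expect_equal(sd(px), 2 / 3, tolerance = 1e-12)
  spiked <- satellite_retrievals("L1", d, "AATSR", 10, px)
  expect_equal(nrow(homogeneity_filter(spiked)), 0)
  # alternating 10 / 10.2: SD ~ 0.1 -> keep
  px2 <- matrix(rep_len(c(10, 10.2), 9), 1, 9)
  expect_lt(sd(px2), 0.5)
  alt <- satellite_retrievals("L1", d, "AATSR", 10, px2)
  expect_equal(nrow(homogeneity_filter(alt)), 1)
  # a missing pixel in a 3x3 array is dropped conservatively
  px3 <- matrix(10, 1, 9); px3[1, 3] <- NA
  holed <- satellite_retrievals("L1", d, "AATSR", 10, px3)
  expect_equal(nrow(homogeneity_filter(holed)), 0)
  # degenerate 1x1 products pass untouched
  single <- satellite_retrievals("L1", d, "AVHRR", 10, 14)
  expect_equal(nrow(homogeneity_filter(single)), 1)
  # exactly at the limit is kept (strict > rejection)
  at_limit <- satellite_retrievals("L1", d, "AATSR", 10,
                                   matrix(10 + c(rep(0.25, 4), rep(-0.25, 4), 0) *
                                            0.5 / sd(c(rep(0.25, 4), rep(-0.25, 4), 0)),
                                          1, 9))
  sd_at <- laketherm:::retrieval_pixel_sd(at_limit)
  expect_equal(sd_at, 0.5, tolerance = 1e-12)
  expect_equal(nrow(homogeneity_filter(at_limit)), 1)
})

test_that("skin-to-bulk applies sensor-specific linear corrections", {
  d <- as.Date("2000-07-01")
  skin <- make_retrievals(d, 14, sensor = "AVHRR", skin = TRUE)
  # identity when not flagged as skin
  notskin <- make_retrievals(d, 14, skin = FALSE)
  expect_equal(skin_to_bulk(notskin)$temp_c, 14)
  # slope 1, intercept +0.3
  corr <- data.frame(sensor = "AVHRR", slope = 1, intercept = 0.3)
  expect_equal(skin_to_bulk(skin, corr)$temp_c, 14.3)
  # two sensors, same night, each mapped by its own factors
  both <- rbind(make_retrievals(d, 14, sensor = "AVHRR", skin = TRUE),
                make_retrievals(d, 14, sensor = "AATSR", skin = TRUE))
  corr2 <- data.frame(sensor = c("AVHRR", "AATSR"), slope = c(1, 1.01),
                      intercept = c(0.3, 0.1))
  out <- skin_to_bulk(both, corr2)
  expect_equal(out$temp_c[out$sensor == "AVHRR"], 14.3)
  expect_equal(out$temp_c[out$sensor == "AATSR"], 14 * 1.01 + 0.1)
  # missing correction: warn and pass through, or error in strict mode
  expect_warning(res <- skin_to_bulk(skin, corr2[2, ]), "no skin-to-bulk")
  expect_equal(res$temp_c, 14)
  expect_error(skin_to_bulk(skin, corr2[2, ], strict = TRUE))
})

test_that("sensor series merge into one date-sorted observation list", {
  a <- data.frame(site_id = "L1", date = as.Date("2000-07-01") + c(0, 4),
                  sensor = "AVHRR", temp_c = c(14, 15))
  b <- data.frame(site_id = "L1", date = as.Date("2000-07-01") + c(2, 4),
                  sensor = "AATSR", temp_c = c(14.5, 15.2))
  m <- merge_sensor_series(a, b)
  expect_equal(nrow(m), 4)
  expect_false(is.unsorted(m$date))
  # same-date observations from different sensors are both retained
  expect_equal(sum(m$date == a$date[2]), 2)
  expect_equal(merge_sensor_series(a), a)
})

test_that("the yearly smoother is exact on constants and lines, robust to spikes", {
  cfg <- lowess_config()
  d <- as.Date("2000-01-05") + seq(0, 350, by = 7)
  const <- lowess_fit_year(d, rep(15, length(d)), cfg)
  expect_equal(const(d + 3), rep(15, length(d)), tolerance = 1e-9)
  # straight line reproduced at observation dates
  y_line <- 5 + 0.02 * seq_along(d)
  linear <- lowess_fit_year(d, y_line, cfg)
  expect_equal(linear(d), y_line, tolerance = 1e-6)
  # one +10 degC outlier among 50 smooth points: robust fit shrinks it
  d50 <- as.Date("2000-06-01") + seq(0, 98, by = 2)
  curve <- 20 + 3 * sin(seq_along(d50) / 8)
  y <- curve; y[25] <- y[25] + 10
  robust <- lowess_fit_year(d50, y, cfg)
  plain <- lowess_fit_year(d50, y, lowess_config(robust_iterations = 0))
  dev_robust <- abs(robust(d50[25]) - curve[25])
  dev_plain <- abs(plain(d50[25]) - curve[25])
  expect_lt(dev_robust, 10 / 2)
  expect_lt(dev_robust, dev_plain)
  # too few points: no smoother
  expect_null(lowess_fit_year(d50[1:3], y[1:3], cfg))
})

test_that("satellite seasonal mean needs 20 in-window retrievals", {
  w <- jas_window()
  obs <- function(k) data.frame(
    site_id = "L1", date = w$start_date + round(seq(0, 91, length.out = k)),
    sensor = "AATSR", temp_c = rep(15, k))
  m19 <- satellite_seasonal_mean(obs(19), w)
  expect_identical(m19$method, "insufficient_data")
  expect_true(is.na(m19$mean))
  m20 <- satellite_seasonal_mean(obs(20), w)
  expect_identical(m20$method, "lowess_smoothed")
  expect_equal(m20$mean, 15, tolerance = 1e-9)
  # 40 retrievals on a noiseless late-summer parabola recover its window mean
  t0 <- as.numeric(as.Date("2000-08-05"))
  f <- function(d) 23 - 0.001 * (as.numeric(d) - t0)^2
  d40 <- w$start_date + round(seq(0, 91, length.out = 40))
  m40 <- satellite_seasonal_mean(
    data.frame(site_id = "L1", date = d40, sensor = "AATSR",
               temp_c = f(d40)), w)
  true_mean <- mean(f(daily_grid(w)))
  expect_lt(abs(m40$mean - true_mean), 0.05)
})

test_that("screening commutes and removing observations never creates a mean", {
  set.seed(11)
  par <- lake_curve_params(noise_sd = 0, years = 2000, seed = 3)
  syn <- synth_daily_series(par)
  r <- synth_satellite_retrievals(syn$truth, sat_obs_params(
    cloud_prob = 0.5, inhomog_prob = 0.2, zenith_range = c(0, 60), seed = 5))
  ab <- homogeneity_filter(zenith_filter(r))
  ba <- zenith_filter(homogeneity_filter(r))
  expect_identical(rownames(ab), rownames(ba))
  # monotone completeness
  w <- jas_window()
  obs <- skin_to_bulk(screen_retrievals(r),
                      data.frame(sensor = c("AVHRR", "AATSR"), slope = 1,
                                 intercept = 0.3))
  full <- satellite_seasonal_mean(obs, w)
  expect_false(is.na(full$mean))
  thin <- obs[seq(1, nrow(obs), by = 12), ]
  reduced <- satellite_seasonal_mean(thin, w)
  expect_true(is.na(reduced$mean) || reduced$n_obs_in_window <= full$n_obs_in_window)
  # mean invariant to observation ordering
  shuf <- obs[sample(nrow(obs)), ]
  expect_equal(satellite_seasonal_mean(shuf, w)$mean, full$mean)
})

test_that("lowess smoothing resists spike corruption better than a raw mean", {
  w <- jas_window()
  par <- lake_curve_params(noise_sd = 0.2, years = 2000, seed = 9)
  syn <- synth_daily_series(par)
  r <- synth_satellite_retrievals(syn$truth, sat_obs_params(
    cloud_prob = 0.6, inhomog_prob = 0, zenith_range = c(0, 40), seed = 13))
  obs <- skin_to_bulk(screen_retrievals(r),
                      data.frame(sensor = c("AVHRR", "AATSR"), slope = 1,
                                 intercept = 0.3))
  clean_mean <- satellite_seasonal_mean(obs, w)$mean
  in_win <- which(obs$date >= w$start_date & obs$date <= w$end_date)
  set.seed(21)
  spike <- sample(in_win, ceiling(0.05 * length(in_win)))
  corrupted <- obs
  corrupted$temp_c[spike] <- corrupted$temp_c[spike] + 10
  shift_lowess <- abs(satellite_seasonal_mean(corrupted, w)$mean - clean_mean)
  shift_raw <- abs(mean(corrupted$temp_c[in_win]) - mean(obs$temp_c[in_win]))
  expect_lt(shift_lowess, shift_raw)
})
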