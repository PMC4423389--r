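# Independent brute-force oracle: per-day piecewise-linear evaluation over
# the window grid, written against the chord formula directly (no approx()).
# Requires observations bracketing the window and strictly increasing dates.
brute_force_seasonal_mean <- function(dates, temps, window) {
  grid <- seq(window$start_date, window$end_date, by = "day")
  x <- as.numeric(dates)
  y <- temps
  vals <- vapply(as.numeric(grid), function(d) {
    j <- max(which(x <= d))
    if (x[j] == d) return(y[j])
    y[j] + (y[j + 1] - y[j]) * (d - x[j]) / (x[j + 1] - x[j])
  }, numeric(1))
  mean(vals)
}

# Random irregular series bracketing the given window with at least two
# in-window observations, unique dates.
random_bracketing_series <- function(seed, window, n = 12) {
  set.seed(seed)
  lo <- window$start_date - 30
  inwin <- seq(window$start_date, window$end_date, by = "day")
  d <- c(lo + sample(0:29, 1),                  # on/before the window start
         sample(inwin, max(2, n - 2)),          # >= 2 in-window samples
         window$end_date + sample(0:29, 1))     # on/after the window end
  d <- sort(unique(d))
  temps <- cumsum(c(stats::runif(1, 8, 22), stats::rnorm(length(d) - 1, 0, 1.5)))
  temperature_series(d, temps, plausible_range = NULL)
}

# A clean temperate JAS setup reused across tests.
jas_window <- function(year = 2000) summer_window(45, year)
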