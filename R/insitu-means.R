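new_seasonal_mean <- function(site_id, year, mean = NA_real_,
                              n_obs_in_window = 0L, max_gap = NA_real_,
                              mean_gap = NA_real_,
                              method = "insufficient_data", log = NULL) {
  structure(
    list(site_id = site_id, year = as.integer(year), mean = mean,
         n_obs_in_window = as.integer(n_obs_in_window), max_gap = max_gap,
         mean_gap = mean_gap, method = method, log = log),
    class = "seasonal_mean"
  )
}

#' @export
print.seasonal_mean <- function(x, ...) {
  cat(sprintf("<seasonal_mean %s %d: %s (%s; n=%d)>\n", x$site_id, x$year,
              if (is.na(x$mean)) "NA" else sprintf("%.3f degC", x$mean),
              x$method, x$n_obs_in_window))
  invisible(x)
}

# TRUE where the series has an anchor on/before the window start and
# on/after the window end (bracketing observations outside the window count)
.coverage <- function(series, window) {
  list(start = length(series$dates) > 0 && min(series$dates) <= window$start_date,
       end   = length(series$dates) > 0 && max(series$dates) >= window$end_date)
}

#' Linearly interpolate a series onto the daily grid of a window
#'
#' Creates one value per calendar day of the window by connecting successive
#' observations with straight chords. Observations outside the window may
#' anchor the interpolation across the boundary: the chord from the last
#' pre-window sample to the first in-window sample supplies the boundary-day
#' values. Daily values on observation dates equal the observations exactly.
#'
#' @param series a \code{temperature_series} (deduplicated internally).
#' @param window a \code{seasonal_window}.
#' @return Data frame with columns \code{date} and \code{temp_c}, one row per
#'   grid day.
#' @seealso [extrapolate_boundary()] for seasons whose sampling stops short
#'   of a window boundary.
#' @export
interpolate_daily <- function(series, window) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(window, "seasonal_window"))
  series <- dedupe_daily(series)
  cov <- .coverage(series, window)
  if (!cov$start || !cov$end) {
    stop(structure(
      class = c("laketherm_needs_extrapolation", "error", "condition"),
      list(message = paste0(
             "sampling does not span the window (missing ",
             paste(c("start", "end")[!c(cov$start, cov$end)], collapse = " and "),
             "); use extrapolate_boundary()"),
           call = sys.call(-1))))
  }
  grid <- daily_grid(window)
  temp <- stats::approx(as.numeric(series$dates), series$temp_c,
                        xout = as.numeric(grid))$y
  data.frame(date = grid, temp_c = temp)
}

#' Sampling-gap statistics within a seasonal window
#'
#' Gaps are the day counts between sequential sampling dates, computed only
#' for samples that fall inside the seasonal bounds; boundary-to-sample
#' distances are not counted. With fewer than two in-window samples both
#' statistics are undefined.
#'
#' @inheritParams interpolate_daily
#' @return List with \code{max_gap} and \code{mean_gap} (days, \code{NA} when
#'   undefined).
#' @export
gap_statistics <- function(series, window) {
  series <- dedupe_daily(series)
  d <- series$dates[series$dates >= window$start_date &
                      series$dates <= window$end_date]
  if (length(d) < 2) return(list(max_gap = NA_real_, mean_gap = NA_real_))
  gaps <- as.numeric(diff(d))
  list(max_gap = max(gaps), mean_gap = mean(gaps))
}

#' Fit the pooled day-of-year seasonal parabola for a site
#'
#' All observations for one site and depth, pooled across years by
#' day-of-year (DoY), are fitted with ordinary least squares to
#' \code{temperature = a*DoY^2 + b*DoY + c}. The fit is a generic
#' representation of the site's seasonal cycle, used to extend years whose
#' sampling does not reach the window boundaries.
#'
#' R-squared is 1 - SSE/SST about the mean of the pooled points; a perfect
#' fit to constant data (SST = 0) is reported as 1.
#'
#' @param series a \code{temperature_series} pooling all years for the
#'   site/depth.
#' @return A \code{seasonal_parabola}: coefficients \code{a} (degC/day^2),
#'   \code{b} (degC/day), \code{c} (degC), \code{r_squared},
#'   \code{n_points}, \code{doy_domain}, and OLS standard errors \code{se}.
#' @export
fit_seasonal_parabola <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  doy <- .doy(series$dates)
  if (length(unique(doy)) < 3) {
    stop(structure(
      class = c("laketherm_insufficient_data", "error", "condition"),
      list(message = "need >= 3 distinct day-of-year values to fit a parabola",
           call = sys.call(-1))))
  }
  y <- series$temp_c
  fit <- stats::lm(y ~ I(doy^2) + doy)
  cf <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(
    list(a = unname(cf[["I(doy^2)"]]), b = unname(cf[["doy"]]),
         c = unname(cf[["(Intercept)"]]),
         r_squared = r2, n_points = length(y), doy_domain = range(doy),
         se = c(a = unname(se["I(doy^2)"]), b = unname(se["doy"]),
                c = unname(se["(Intercept)"]))),
    class = "seasonal_parabola"
  )
}

#' @export
print.seasonal_parabola <- function(x, ...) {
  cat(sprintf(
    "<seasonal_parabola T = %.6g*DoY^2 + %.6g*DoY + %.6g (R2 = %.4f, n = %d)>\n",
    x$a, x$b, x$c, x$r_squared, x$n_points))
  invisible(x)
}

#' Evaluate a seasonal parabola at day-of-year values
#'
#' @param object a \code{seasonal_parabola}.
#' @param doy day-of-year values (1..366).
#' @param ... unused.
#' @return Temperatures, degrees Celsius.
#' @export
predict.seasonal_parabola <- function(object, doy, ...) {
  object$a * doy^2 + object$b * doy + object$c
}

#' Shift a seasonal parabola vertically through an anchor observation
#'
#' Adjusts only the intercept \code{c} so the curve intersects the anchor
#' point: \code{c' = T_anchor - a*DoY^2 - b*DoY}. Curvature and slope are
#' untouched, so the shifted curve keeps the pooled seasonal shape.
#'
#' @param parabola a \code{seasonal_parabola}.
#' @param doy day-of-year of the anchor observation.
#' @param temp_c temperature of the anchor observation.
#' @return The shifted \code{seasonal_parabola}.
#' @export
shift_parabola <- function(parabola, doy, temp_c) {
  stopifnot(inherits(parabola, "seasonal_parabola"))
  parabola$c <- temp_c - parabola$a * doy^2 - parabola$b * doy
  parabola
}

.log_entry <- function(site_id, year, side, parabola, period) {
  data.frame(site_id = site_id, year = as.integer(year), side = side,
             a = parabola$a, b = parabola$b, c = parabola$c,
             r_squared = parabola$r_squared,
             period_start = period[1], period_end = period[2],
             stringsAsFactors = FALSE)
}

#' Complete a truncated season with the shifted pooled parabola
#'
#' For a year whose sampling starts after the window opens (and/or stops
#' before it closes), daily values for the uncovered head (tail) of the grid
#' are taken from the pooled seasonal parabola shifted vertically to pass
#' through the first (last) sample; the covered span is linearly
#' interpolated as usual. The two sides are shifted independently. Each
#' extrapolated side is recorded in a processing-log entry carrying the
#' shifted equation, the period covered, and the pooled fit's R-squared.
#'
#' @inheritParams interpolate_daily
#' @param parabola the site's pooled \code{seasonal_parabola}.
#' @return List with \code{daily} (data frame \code{date}, \code{temp_c} over
#'   the full grid), \code{sides} (character, which boundaries were
#'   extrapolated), and \code{log} (data frame of log entries, one per side).
#' @export
extrapolate_boundary <- function(series, window, parabola) {
  stopifnot(inherits(parabola, "seasonal_parabola"))
  series <- dedupe_daily(series)
  if (length(series$dates) == 0 ||
      max(series$dates) < window$start_date ||
      min(series$dates) > window$end_date) {
    stop(structure(
      class = c("laketherm_insufficient_data", "error", "condition"),
      list(message = "no observation inside the window; cannot anchor extrapolation",
           call = sys.call(-1))))
  }
  grid <- daily_grid(window)
  temp <- rep(NA_real_, length(grid))
  first <- min(series$dates); last <- max(series$dates)
  cov <- .coverage(series, window)
  sides <- character(0)
  logs <- list()

  mid <- grid >= max(window$start_date, first) &
    grid <= min(window$end_date, last)
  if (any(mid)) {
    temp[mid] <- stats::approx(as.numeric(series$dates), series$temp_c,
                               xout = as.numeric(grid[mid]))$y
  }
  if (!cov$start) {
    head_idx <- grid < first
    anchor <- shift_parabola(parabola, .doy(first),
                             series$temp_c[which.min(series$dates)])
    temp[head_idx] <- predict(anchor, .doy(grid[head_idx]))
    sides <- c(sides, "start")
    logs[["start"]] <- .log_entry(series$site_id, window$year, "start",
                                  anchor, c(min(grid), first - 1))
  }
  if (!cov$end) {
    tail_idx <- grid > last
    anchor <- shift_parabola(parabola, .doy(last),
                             series$temp_c[which.max(series$dates)])
    temp[tail_idx] <- predict(anchor, .doy(grid[tail_idx]))
    sides <- c(sides, "end")
    logs[["end"]] <- .log_entry(series$site_id, window$year, "end",
                                anchor, c(last + 1, max(grid)))
  }
  list(daily = data.frame(date = grid, temp_c = temp), sides = sides,
       log = if (length(logs)) do.call(rbind, unname(logs)) else NULL)
}

#' Harmonized in situ seasonal mean for one lake-year
#'
#' Combines daily linear interpolation (and, where sampling stops short of a
#' window boundary, parabolic extrapolation) into one daily temperature
#' vector over the window grid and returns its arithmetic mean together with
#' in-window gap statistics and a method flag.
#'
#' @inheritParams interpolate_daily
#' @param parabola optional pooled \code{seasonal_parabola} enabling
#'   extrapolation of truncated seasons; without it such seasons yield
#'   \code{method = "insufficient_data"}.
#' @param min_obs minimum in-window observations required to attempt a mean.
#' @return A \code{seasonal_mean}: \code{mean} (degC, \code{NA} when the
#'   method is \code{insufficient_data}), \code{n_obs_in_window},
#'   \code{max_gap}, \code{mean_gap}, \code{method} (one of
#'   \code{"interpolated"}, \code{"interpolated+extrapolated_start"},
#'   \code{"interpolated+extrapolated_end"},
#'   \code{"interpolated+extrapolated_both"}, \code{"insufficient_data"}),
#'   and \code{log} (extrapolation log entries or \code{NULL}).
#' @export
insitu_seasonal_mean <- function(series, window, parabola = NULL,
                                 min_obs = 2) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(window, "seasonal_window"))
  series <- dedupe_daily(series)
  gaps <- gap_statistics(series, window)
  n_in <- sum(series$dates >= window$start_date &
                series$dates <= window$end_date)
  base <- new_seasonal_mean(series$site_id, window$year,
                            n_obs_in_window = n_in,
                            max_gap = gaps$max_gap, mean_gap = gaps$mean_gap)
  if (n_in < min_obs) return(base)
  cov <- .coverage(series, window)
  if (cov$start && cov$end) {
    daily <- interpolate_daily(series, window)
    base$mean <- mean(daily$temp_c)
    base$method <- "interpolated"
    return(base)
  }
  if (is.null(parabola)) return(base)
  ext <- tryCatch(extrapolate_boundary(series, window, parabola),
                  laketherm_insufficient_data = function(e) NULL)
  if (is.null(ext)) return(base)
  base$mean <- mean(ext$daily$temp_c)
  base$method <- paste0("interpolated+extrapolated_",
                        if (length(ext$sides) == 2) "both" else ext$sides)
  base$log <- ext$log
  base
}

#' Time-averaged bias of linear interpolation against a known truth
#'
#' Computes the continuous time-average over \code{[from, to]} of the
#' difference between the piecewise-linear interpolant of a series and a
#' known underlying temperature curve. Integration is per-segment Simpson
#' quadrature on the interpolant's knots, exact whenever the truth is
#' quadratic in time. On a quadratic trajectory with curvature \code{a}
#' sampled every \code{h} days over a whole number of sampling intervals,
#' this bias equals \code{a*h^2/6} (negative for concave summer peaks):
#' sparse sampling of a peaked season systematically underestimates the
#' seasonal mean.
#'
#' @param series a \code{temperature_series} whose observations span
#'   \code{[from, to]}.
#' @param from,to averaging bounds, \code{Date} or numeric days.
#' @param truth function of numeric date (days, same axis as
#'   \code{as.numeric(series$dates)}) returning the true temperature.
#' @return The time-averaged (interpolant - truth), degrees Celsius.
#' @export
interpolation_bias <- function(series, from, to, truth) {
  series <- dedupe_daily(series)
  x <- as.numeric(series$dates)
  from <- as.numeric(from); to <- as.numeric(to)
  if (to <= from) stop("`to` must exceed `from`")
  if (min(x) > from || max(x) < to) {
    stop("observations must span the averaging interval")
  }
  interp <- stats::approxfun(x, series$temp_c)
  knots <- sort(unique(c(from, to, x[x > from & x < to])))
  g <- function(t) interp(t) - truth(t)
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    l <- knots[i]; r <- knots[i + 1]
    total <- total + (r - l) * (g(l) + 4 * g((l + r) / 2) + g(r)) / 6
  }
  total / (to - from)
}
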