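#' Subsample a daily series at a fixed interval from a chosen start date
#'
#' Emulates a monitoring program that samples every \code{interval} days:
#' observations are taken at \code{first_sample_date}, then every
#' \code{interval} days up to the end of the daily record.
#'
#' @param daily a daily \code{temperature_series} (one value per day).
#' @param interval sampling interval in days (>= 1).
#' @param first_sample_date date of the first sample; must be a day covered
#'   by the series.
#' @return A \code{temperature_series} of the sampled observations.
#' @export
subsample <- function(daily, interval, first_sample_date) {
  stopifnot(inherits(daily, "temperature_series"), interval >= 1)
  first_sample_date <- as.Date(first_sample_date)
  if (first_sample_date < min(daily$dates) ||
      first_sample_date > max(daily$dates)) {
    stop("`first_sample_date` is outside the daily record")
  }
  wanted <- seq(first_sample_date, max(daily$dates), by = interval)
  idx <- match(wanted, daily$dates)
  if (anyNA(idx)) stop("the series is not daily over the sampling span")
  temperature_series(daily$dates[idx], daily$temp_c[idx],
                     site_id = daily$site_id, depth_label = daily$depth_label,
                     plausible_range = NULL)
}

# the 28-31 candidate start dates: the calendar month preceding the window
.start_month_dates <- function(window) {
  prev_end <- window$start_date - 1
  seq(as.Date(format(prev_end, "%Y-%m-01")), prev_end, by = "day")
}

#' Seasonal-mean error as a function of sampling interval
#'
#' Bootstrap assessment of the error that sparse sampling introduces into
#' interpolated seasonal means. For each sampling interval, simulated
#' monitoring datasets are drawn from a daily record: the first sample date
#' is chosen uniformly at random within the calendar month preceding the
#' seasonal window (June for a JAS window), subsequent samples follow every
#' \code{interval} days, and the interpolated seasonal mean of each
#' simulated dataset is compared against the "true" mean computed from the
#' full daily record (a sampling interval of 1 day, which by construction
#' has zero error). Errors are signed, estimate minus truth; on a concave
#' (peaked) summer trajectory linear interpolation under-runs the curve, so
#' mean errors are negative and grow in magnitude with the interval.
#'
#' Because replicate variation is driven entirely by the random start date,
#' an exact enumeration mode averaging over all candidate start dates with
#' equal weight is provided as the reference against which Monte Carlo runs
#' converge.
#'
#' @param daily a daily \code{temperature_series} covering the start month
#'   and the window (sampling past the window end ensures interpolation
#'   always brackets the window).
#' @param window a \code{seasonal_window}.
#' @param intervals sampling intervals in days to assess.
#' @param n_replicates simulated datasets per interval (Monte Carlo mode).
#' @param seed integer seed driving the random start dates.
#' @param method \code{"montecarlo"} (default) or \code{"enumerate"} (exact
#'   average over all start dates; \code{n_replicates} ignored).
#' @return A \code{gap_error_curve}: data frame with columns
#'   \code{interval}, \code{mean_error}, \code{sd_error}, \code{n}, with the
#'   seed and method recorded as attributes.
#' @export
gap_error_simulation <- function(daily, window, intervals = 1:34,
                                 n_replicates = 2000, seed = NULL,
                                 method = c("montecarlo", "enumerate")) {
  method <- match.arg(method)
  stopifnot(inherits(daily, "temperature_series"),
            inherits(window, "seasonal_window"), all(intervals >= 1),
            n_replicates >= 1)
  starts <- .start_month_dates(window)
  if (min(daily$dates) > min(starts) || max(daily$dates) < window$end_date) {
    stop("daily record must cover the start month through the window end")
  }
  grid <- daily_grid(window)
  idx <- match(grid, daily$dates)
  if (anyNA(idx)) stop("daily record has missing days inside the window")
  true_mean <- mean(daily$temp_c[idx])
  if (!is.null(seed)) set.seed(seed)

  # the error is a deterministic function of (interval, start date), so
  # compute each distinct start date once and resample from those values
  err_by_start <- function(interval) {
    vapply(seq_along(starts), function(i) {
      sub <- subsample(daily, interval, starts[i])
      est <- insitu_seasonal_mean(sub, window)
      if (is.na(est$mean)) NA_real_ else est$mean - true_mean
    }, numeric(1))
  }

  rows <- lapply(intervals, function(h) {
    errs <- err_by_start(h)
    if (method == "enumerate") {
      drawn <- errs
    } else {
      drawn <- errs[sample.int(length(starts), n_replicates, replace = TRUE)]
    }
    drawn <- drawn[!is.na(drawn)]
    data.frame(interval = h, mean_error = mean(drawn),
               sd_error = stats::sd(drawn), n = length(drawn))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "n_replicates") <- if (method == "enumerate") length(starts) else
    n_replicates
  class(out) <- c("gap_error_curve", "data.frame")
  out
}
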