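#' Parameters of a synthetic seasonal lake-temperature curve
#'
#' Describes a multi-year daily "true" surface temperature trajectory with a
#' smooth concave summer peak, optional linear interannual trend, and
#' additive Gaussian observation noise. Two curve families are provided:
#' \code{"parabolic"} (quadratic in day-of-year around the peak, for which
#' interpolation biases have closed forms) and \code{"sinusoidal"} (annual
#' harmonic, closer in shape to real temperate lakes). Defaults emulate a
#' temperate dimictic lake: peak near 24 degC in early August, window-edge
#' temperatures several degrees below the peak.
#'
#' @param shape \code{"parabolic"} or \code{"sinusoidal"}.
#' @param peak_temp peak summer temperature, degC, in the first year.
#' @param peak_doy day-of-year of the seasonal peak.
#' @param curvature magnitude of the quadratic coefficient, degC/day^2
#'   (> 0; the curve itself is concave, T = peak - curvature*(DoY-peak)^2).
#' @param amplitude semi-amplitude of the sinusoidal family, degC.
#' @param noise_sd SD of additive daily observation noise, degC (>= 0).
#' @param annual_trend linear warming trend, degC per year.
#' @param years calendar years covered.
#' @param latitude decimal degrees, used to resolve each year's summer
#'   window.
#' @param seed integer seed making the generated noise reproducible.
#' @return A \code{lake_curve_params} list.
#' @export
lake_curve_params <- function(shape = c("parabolic", "sinusoidal"),
                              peak_temp = 24, peak_doy = 215,
                              curvature = 0.0025, amplitude = 9,
                              noise_sd = 0.5, annual_trend = 0,
                              years = 1985:2009, latitude = 45, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(noise_sd >= 0, curvature > 0, amplitude > 0, length(years) >= 1)
  structure(list(shape = shape, peak_temp = peak_temp, peak_doy = peak_doy,
                 curvature = curvature, amplitude = amplitude,
                 noise_sd = noise_sd, annual_trend = annual_trend,
                 years = as.integer(years), latitude = latitude,
                 seed = as.integer(seed)),
            class = "lake_curve_params")
}

# noiseless curve value at given dates under params
.curve_truth <- function(params, dates) {
  doy <- .doy(dates)
  yr <- as.POSIXlt(dates)$year + 1900L
  trend <- params$annual_trend * (yr - params$years[1])
  if (params$shape == "parabolic") {
    params$peak_temp + trend - params$curvature * (doy - params$peak_doy)^2
  } else {
    params$peak_temp + trend -
      params$amplitude * (1 - cos(2 * pi * (doy - params$peak_doy) / 365.25))
  }
}

#' Generate a daily synthetic temperature series with known truth
#'
#' Produces the full daily record (1 January of the first year through 31
#' December of the last), both noiseless and with additive N(0, noise_sd^2)
#' noise, plus the exact per-year summer-window mean of the noiseless curve
#' (the estimand every downstream estimator is scored against, defined as
#' the mean of the noiseless daily values over the window grid).
#'
#' @param params a [lake_curve_params()].
#' @param site_id identifier attached to the generated series.
#' @return List with \code{series} (noisy \code{temperature_series}),
#'   \code{truth} (noiseless \code{temperature_series}), \code{truth_fun}
#'   (function of dates returning the noiseless curve), and
#'   \code{true_window_means} (data frame \code{year}, \code{true_mean}).
#' @export
synth_daily_series <- function(params, site_id = "synthetic_lake") {
  stopifnot(inherits(params, "lake_curve_params"))
  set.seed(params$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(params$years))),
               as.Date(sprintf("%d-12-31", max(params$years))), by = "day")
  truth <- .curve_truth(params, dates)
  noisy <- truth + if (params$noise_sd > 0)
    stats::rnorm(length(dates), 0, params$noise_sd) else 0
  twm <- do.call(rbind, lapply(params$years, function(y) {
    grid <- daily_grid(summer_window(params$latitude, y))
    data.frame(year = y, true_mean = mean(truth[match(grid, dates)]))
  }))
  list(
    series = temperature_series(dates, noisy, site_id = site_id,
                                plausible_range = NULL),
    truth = temperature_series(dates, truth, site_id = site_id,
                               plausible_range = NULL),
    truth_fun = function(d) .curve_truth(params, as.Date(d)),
    true_window_means = twm
  )
}

#' Thin a daily series into an irregular in situ sampling schedule
#'
#' Emulates realistic monitoring programs: a nominal sampling cadence with
#' uniform day jitter, Bernoulli dropout (missed visits), and optional
#' truncation of the observed period (e.g. an early freeze-up cutting the
#' season short, forcing downstream extrapolation).
#'
#' @param daily a daily \code{temperature_series}.
#' @param interval nominal sampling interval, days.
#' @param jitter maximum uniform day shift applied to each scheduled visit.
#' @param dropout probability that a scheduled visit is missed.
#' @param truncate optional 2-element date range; observations outside it
#'   are discarded.
#' @param seed integer seed.
#' @return A \code{temperature_series}.
#' @export
synth_insitu_sampling <- function(daily, interval, jitter = 0, dropout = 0,
                                  truncate = NULL, seed = NULL) {
  stopifnot(inherits(daily, "temperature_series"), interval >= 1,
            jitter >= 0, dropout >= 0, dropout <= 1)
  if (!is.null(seed)) set.seed(seed)
  sched <- seq(min(daily$dates), max(daily$dates), by = interval)
  if (jitter > 0) {
    sched <- sched + sample(seq(-jitter, jitter), length(sched),
                            replace = TRUE)
  }
  if (dropout > 0) {
    sched <- sched[stats::runif(length(sched)) >= dropout]
  }
  if (!is.null(truncate)) {
    truncate <- as.Date(truncate)
    sched <- sched[sched >= truncate[1] & sched <= truncate[2]]
  }
  sched <- sort(unique(sched))
  idx <- match(sched, daily$dates)
  keep <- !is.na(idx)
  temperature_series(sched[keep], daily$temp_c[idx[keep]],
                     site_id = daily$site_id, depth_label = daily$depth_label,
                     plausible_range = NULL)
}

#' Parameters of the synthetic satellite observation process
#'
#' Controls how nightly thermal-infrared retrievals are simulated from a
#' true bulk-temperature curve: cloud dropout, the mean and spread of the
#' (bulk - skin) temperature offset, within-array pixel noise, occasional
#' cloud/land-contaminated arrays whose spread trips the homogeneity test,
#' the view-zenith distribution, and the active sensors with their array
#' sizes.
#'
#' @param cloud_prob probability a nightly overpass is lost to cloud.
#' @param skin_offset_mean mean bulk-minus-skin offset, degC (skin is cooler
#'   at night, so typically positive).
#' @param skin_offset_sd night-to-night SD of the offset, degC.
#' @param pixel_sd within-array pixel noise SD, degC.
#' @param inhomog_prob probability an array is contaminated (its pixel SD is
#'   pushed well above 0.5 degC).
#' @param inhomog_magnitude half-range of the contamination pattern, degC.
#' @param zenith_range uniform range of view zenith angles, degrees.
#' @param sensors data frame \code{sensor}, \code{start}, \code{end},
#'   \code{array_size} (1 or 3); \code{NULL} selects a 1x1 AVHRR-style plus
#'   a 3x3 ATSR-style instrument, both active over the whole record.
#' @param seed integer seed.
#' @return A \code{sat_obs_params} list.
#' @export
sat_obs_params <- function(cloud_prob = 0.3, skin_offset_mean = 0.3,
                           skin_offset_sd = 0.1, pixel_sd = 0.05,
                           inhomog_prob = 0.05, inhomog_magnitude = 2,
                           zenith_range = c(0, 55), sensors = NULL,
                           seed = 1) {
  stopifnot(cloud_prob >= 0, cloud_prob <= 1, inhomog_prob >= 0,
            inhomog_prob <= 1, pixel_sd >= 0, skin_offset_sd >= 0,
            length(zenith_range) == 2)
  structure(list(cloud_prob = cloud_prob, skin_offset_mean = skin_offset_mean,
                 skin_offset_sd = skin_offset_sd, pixel_sd = pixel_sd,
                 inhomog_prob = inhomog_prob,
                 inhomog_magnitude = inhomog_magnitude,
                 zenith_range = zenith_range, sensors = sensors,
                 seed = as.integer(seed)),
            class = "sat_obs_params")
}

#' Simulate nighttime satellite retrievals from a true temperature curve
#'
#' For every day of the daily record and every active sensor, a candidate
#' nighttime retrieval is generated and then lost to cloud with probability
#' \code{cloud_prob}. Surviving retrievals carry a skin temperature (truth
#' minus the bulk-skin offset plus nightly noise), a pixel array (skin plus
#' per-pixel noise; 1x1 products carry only the center pixel), a uniform
#' view zenith angle, and -- with probability \code{inhomog_prob} -- a
#' contamination pattern of alternating +/- \code{inhomog_magnitude} that
#' guarantees the array fails the 0.5 degC homogeneity test.
#'
#' @param daily a daily \code{temperature_series} of true bulk temperatures.
#' @param params a [sat_obs_params()].
#' @return A retrievals data frame (see [satellite_retrievals()]).
#' @export
synth_satellite_retrievals <- function(daily, params = sat_obs_params()) {
  stopifnot(inherits(daily, "temperature_series"),
            inherits(params, "sat_obs_params"))
  set.seed(params$seed)
  sensors <- params$sensors
  if (is.null(sensors)) {
    sensors <- data.frame(
      sensor = c("AVHRR", "AATSR"),
      start = rep(min(daily$dates), 2), end = rep(max(daily$dates), 2),
      array_size = c(1L, 3L), stringsAsFactors = FALSE)
  }
  contam_pattern <- rep_len(c(1, -1), 9) * params$inhomog_magnitude
  pieces <- lapply(seq_len(nrow(sensors)), function(s) {
    active <- daily$dates >= sensors$start[s] & daily$dates <= sensors$end[s]
    d <- daily$dates[active]; truth <- daily$temp_c[active]
    clear <- stats::runif(length(d)) >= params$cloud_prob
    d <- d[clear]; truth <- truth[clear]
    n <- length(d)
    if (n == 0) return(NULL)
    skin <- truth - params$skin_offset_mean +
      stats::rnorm(n, 0, params$skin_offset_sd)
    zen <- stats::runif(n, params$zenith_range[1], params$zenith_range[2])
    if (sensors$array_size[s] == 3) {
      px <- skin + matrix(stats::rnorm(9 * n, 0, params$pixel_sd), n, 9)
      contam <- stats::runif(n) < params$inhomog_prob
      if (any(contam)) {
        px[contam, ] <- px[contam, , drop = FALSE] +
          matrix(contam_pattern, sum(contam), 9, byrow = TRUE)
      }
      satellite_retrievals(daily$site_id, d, sensors$sensor[s], zen, px)
    } else {
      satellite_retrievals(daily$site_id, d, sensors$sensor[s], zen, skin)
    }
  })
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  out[order(out$timestamp, out$sensor), , drop = FALSE]
}
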