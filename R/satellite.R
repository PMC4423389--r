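.pixel_cols <- paste0("p", c(t(outer(1:3, 1:3, paste0))))  # p11 p12 .. p33

#' Assemble a table of nighttime satellite retrievals
#'
#' One row per overpass: the timestamp, the sensor, the view zenith angle,
#' the skin flag, and either a 3x3 pixel array of temperatures (multi-pixel
#' radiometer products) or a single center-pixel value (degenerate 1x1
#' products such as the 4-km Pathfinder record, stored in \code{p22}).
#'
#' @param site_id site identifier (recycled).
#' @param timestamp retrieval dates (coerced with \code{as.Date}).
#' @param sensor sensor name per retrieval, e.g. \code{"AVHRR"},
#'   \code{"ATSR2"}, \code{"AATSR"}.
#' @param zenith_deg view zenith angles in degrees, within [0, 90].
#' @param pixels numeric matrix with 9 columns (rows = retrievals, order
#'   p11..p33 row-major) for 3x3 products, or a vector of center-pixel
#'   temperatures for 1x1 products.
#' @param skin logical: are the temperatures skin temperatures needing a
#'   bulk correction? Recycled.
#' @return Data frame with columns \code{site_id}, \code{timestamp},
#'   \code{sensor}, \code{zenith_deg}, \code{skin}, \code{array_size}
#'   (1 or 3) and \code{p11}..\code{p33}.
#' @export
satellite_retrievals <- function(site_id, timestamp, sensor, zenith_deg,
                                 pixels, skin = TRUE) {
  timestamp <- as.Date(timestamp)
  n <- length(timestamp)
  if (is.matrix(pixels)) {
    stopifnot(ncol(pixels) == 9, nrow(pixels) == n)
    px <- pixels
    array_size <- 3L
  } else {
    stopifnot(length(pixels) == n)
    px <- matrix(NA_real_, n, 9)
    px[, 5] <- as.numeric(pixels)
    array_size <- 1L
  }
  colnames(px) <- .pixel_cols
  if (any(!is.na(zenith_deg) & (zenith_deg < 0 | zenith_deg > 90))) {
    stop("zenith angles must lie in [0, 90] degrees")
  }
  out <- data.frame(site_id = rep_len(site_id, n), timestamp = timestamp,
                    sensor = rep_len(sensor, n),
                    zenith_deg = as.numeric(zenith_deg),
                    skin = rep_len(as.logical(skin), n),
                    array_size = rep_len(array_size, n),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(px))
}

#' Discard retrievals acquired at high view zenith angles
#'
#' Pixels acquired at zenith angles greater than 45 degrees are discarded
#' (path length through the atmosphere degrades the thermal retrieval);
#' exactly 45 degrees is retained.
#'
#' @param retrievals a retrievals data frame (see
#'   [satellite_retrievals()]).
#' @param max_zenith cutoff in degrees; retrievals strictly above it are
#'   dropped.
#' @return The retained rows.
#' @export
zenith_filter <- function(retrievals, max_zenith = 45) {
  keep <- !is.na(retrievals$zenith_deg) & retrievals$zenith_deg <= max_zenith
  retrievals[keep, , drop = FALSE]
}

# per-retrieval pixel-array standard deviation; NA for 1x1 or incomplete arrays
retrieval_pixel_sd <- function(retrievals, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  px <- as.matrix(retrievals[, .pixel_cols, drop = FALSE])
  apply_fun <- function(v) {
    if (anyNA(v)) return(NA_real_)
    if (sd_type == "sample") stats::sd(v) else sqrt(mean((v - mean(v))^2))
  }
  out <- apply(px, 1, apply_fun)
  out[retrievals$array_size == 1] <- NA_real_
  out
}

#' Spatial homogeneity screening of 3x3 pixel arrays
#'
#' Rejects any 3x3 array whose pixel standard deviation exceeds 0.5 degrees
#' Celsius -- high spread flags residual cloud or land contamination within
#' the array. The boundary is strict: SD exactly at the limit is kept.
#' Arrays with any missing pixel are dropped (conservative). Degenerate 1x1
#' center-pixel products carry no spatial information and pass untouched;
#' their cloud screening happens upstream in the source product.
#'
#' @inheritParams zenith_filter
#' @param sd_limit rejection threshold in degrees Celsius.
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @return The retained rows.
#' @export
homogeneity_filter <- function(retrievals, sd_limit = 0.5,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(retrievals) == 0) return(retrievals)
  is33 <- retrievals$array_size == 3
  sds <- retrieval_pixel_sd(retrievals, sd_type)
  keep <- !is33 | (!is.na(sds) & sds <= sd_limit)
  retrievals[keep, , drop = FALSE]
}

#' Convert screened retrievals to bulk water temperature observations
#'
#' Satellite radiometers sense the sub-millimeter skin of the water surface,
#' which is systematically cooler at night than the bulk temperature at
#' about 1 m depth. Retrievals flagged as skin temperatures are mapped to
#' bulk by the sensor-specific linear correction
#' \code{bulk = slope * T + intercept}; the numeric factors are calibration
#' products supplied by the user, keyed by sensor. Retrievals without a
#' matching correction pass through unchanged with a warning (or an error in
#' strict mode).
#'
#' @inheritParams zenith_filter
#' @param corrections data frame with columns \code{sensor}, \code{slope}
#'   (> 0) and \code{intercept} (degC), or \code{NULL} for identity.
#' @param statistic which array statistic to correct: the center pixel
#'   (default) or the mean of available pixels.
#' @param strict error (instead of warn) when a skin retrieval has no
#'   correction for its sensor.
#' @return Data frame of observations: \code{site_id}, \code{date},
#'   \code{sensor}, \code{temp_c}.
#' @export
skin_to_bulk <- function(retrievals, corrections = NULL,
                         statistic = c("center", "mean"), strict = FALSE) {
  statistic <- match.arg(statistic)
  if (!is.null(corrections)) {
    stopifnot(all(c("sensor", "slope", "intercept") %in% names(corrections)))
    if (any(corrections$slope <= 0)) stop("correction slopes must be positive")
  }
  px <- as.matrix(retrievals[, .pixel_cols, drop = FALSE])
  temp <- if (statistic == "center") px[, 5] else rowMeans(px, na.rm = TRUE)
  if (nrow(retrievals)) {
    idx <- if (is.null(corrections)) rep(NA_integer_, nrow(retrievals)) else
      match(retrievals$sensor, corrections$sensor)
    uncorrected <- retrievals$skin & is.na(idx)
    if (any(uncorrected)) {
      msg <- paste0("no skin-to-bulk correction for sensor(s): ",
                    paste(unique(retrievals$sensor[uncorrected]), collapse = ", "),
                    "; identity used")
      if (strict) stop(msg) else warning(msg)
    }
    apply_to <- retrievals$skin & !is.na(idx)
    if (any(apply_to)) {
      j <- idx[apply_to]
      temp[apply_to] <- corrections$slope[j] * temp[apply_to] +
        corrections$intercept[j]
    }
  }
  data.frame(site_id = retrievals$site_id, date = retrievals$timestamp,
             sensor = retrievals$sensor, temp_c = temp,
             stringsAsFactors = FALSE)
}

#' Merge screened observation series from several sensors
#'
#' Unions the cloud-free, bulk-corrected observations from multiple
#' radiometer series into a single dataset sorted by date, maximizing the
#' sampling frequency. Same-date observations from different sensors are
#' both retained.
#'
#' @param ... observation data frames as returned by [skin_to_bulk()]
#'   (columns \code{date} and \code{temp_c} at minimum).
#' @return One observation data frame sorted by date.
#' @export
merge_sensor_series <- function(...) {
  pieces <- list(...)
  pieces <- pieces[vapply(pieces, function(p) !is.null(p) && nrow(p) > 0,
                          logical(1))]
  if (length(pieces) == 0) {
    return(data.frame(site_id = character(0), date = as.Date(character(0)),
                      sensor = character(0), temp_c = numeric(0)))
  }
  out <- do.call(rbind, pieces)
  out[order(out$date), , drop = FALSE]
}

#' Smoothing configuration for satellite seasonal means
#'
#' @param span fraction of the year's observations entering each local fit;
#'   an effective floor of 15 points is applied for sparse years, the
#'   smallest window at which the bisquare reweighting reliably outvotes a
#'   single outlying retrieval. The default
#'   0.1 resolves month-scale seasonal structure for dense nightly
#'   retrievals; wide spans flatten the summer peak of the annual cycle and
#'   bias the seasonal mean cold (local linear smoothing bias is
#'   approximately -f''*sigma_w^2/2 for local-window spread sigma_w).
#' @param robust_iterations number of bisquare reweighting passes guarding
#'   the local fits against outliers.
#' @param min_retrievals minimum number of valid in-window retrievals
#'   required before a seasonal mean is emitted (default 20), ensuring the
#'   observations adequately characterize the temperature curve.
#' @return A \code{lowess_config} list.
#' @export
lowess_config <- function(span = 0.1, robust_iterations = 2,
                          min_retrievals = 20) {
  stopifnot(span > 0, span <= 1, robust_iterations >= 0, min_retrievals >= 1)
  structure(list(span = span, robust_iterations = as.integer(robust_iterations),
                 min_retrievals = as.integer(min_retrievals)),
            class = "lowess_config")
}

#' Robust locally weighted regression smoother for one calendar year
#'
#' Fits Cleveland's robust LOWESS (tricube-weighted local linear regression
#' with iterated bisquare reweighting) to one calendar year of observations
#' and returns a function evaluable at arbitrary dates. Between fitted
#' points the smoother is linearly interpolated; outside the observed date
#' range the nearest fitted value is carried flat, so evaluation far beyond
#' the data is deliberately conservative.
#'
#' @param dates observation dates.
#' @param temp_c observed temperatures, degrees Celsius.
#' @param config a [lowess_config()].
#' @return Function mapping dates to smoothed temperatures, or \code{NULL}
#'   when fewer than 4 observations are available.
#' @export
lowess_fit_year <- function(dates, temp_c, config = lowess_config()) {
  stopifnot(inherits(config, "lowess_config"))
  dates <- as.Date(dates)
  ok <- !is.na(dates) & is.finite(temp_c)
  x <- as.numeric(dates[ok]); y <- temp_c[ok]
  n <- length(x)
  if (n < 4) return(NULL)
  eff_span <- max(config$span, min(1, 15 / n))
  # robust iterations are skipped when the initial fit already interpolates
  # the data: a near-zero residual MAD degenerates the bisquare weights
  fit <- stats::lowess(x, y, f = eff_span, iter = 0, delta = 0)
  res_scale <- stats::median(abs(y[order(x)] - fit$y))
  if (config$robust_iterations > 0 &&
      res_scale > 1e-9 * max(1, diff(range(y)))) {
    fit <- stats::lowess(x, y, f = eff_span, iter = config$robust_iterations,
                         delta = 0)
  }
  function(d) {
    stats::approx(fit$x, fit$y, xout = as.numeric(as.Date(d)), rule = 2,
                  ties = mean)$y
  }
}

#' Satellite seasonal mean from screened, merged observations
#'
#' Smooths one calendar year of observations with robust LOWESS and averages
#' the smoothed curve over every day of the seasonal window. A mean is
#' emitted only when at least \code{min_retrievals} valid observations fall
#' inside the window (default 20); otherwise the lake-year is reported as
#' \code{insufficient_data}.
#'
#' @param observations observation data frame (columns \code{date},
#'   \code{temp_c}; optional \code{site_id}).
#' @param window a \code{seasonal_window}.
#' @param config a [lowess_config()].
#' @return A \code{seasonal_mean} with method \code{"lowess_smoothed"} or
#'   \code{"insufficient_data"}.
#' @export
satellite_seasonal_mean <- function(observations, window,
                                    config = lowess_config()) {
  stopifnot(inherits(window, "seasonal_window"))
  site <- if ("site_id" %in% names(observations) && nrow(observations))
    observations$site_id[1] else "site"
  obs <- observations[!is.na(observations$date) &
                        is.finite(observations$temp_c), , drop = FALSE]
  in_win <- obs$date >= window$start_date & obs$date <= window$end_date
  n_in <- sum(in_win)
  d_in <- sort(obs$date[in_win])
  gaps <- if (n_in >= 2) as.numeric(diff(d_in)) else numeric(0)
  base <- new_seasonal_mean(site, window$year, n_obs_in_window = n_in,
                            max_gap = if (length(gaps)) max(gaps) else NA_real_,
                            mean_gap = if (length(gaps)) mean(gaps) else NA_real_)
  if (n_in < config$min_retrievals) return(base)
  yr <- as.POSIXlt(obs$date)$year + 1900L
  smoother <- lowess_fit_year(obs$date[yr == window$year],
                              obs$temp_c[yr == window$year], config)
  if (is.null(smoother)) return(base)
  base$mean <- mean(smoother(daily_grid(window)))
  base$method <- "lowess_smoothed"
  base
}

#' One-call screening of raw retrievals
#'
#' Applies the zenith-angle filter and the spatial homogeneity test; the two
#' screens commute, so order is immaterial.
#'
#' @inheritParams zenith_filter
#' @inheritParams homogeneity_filter
#' @return The retained rows.
#' @export
screen_retrievals <- function(retrievals, max_zenith = 45, sd_limit = 0.5,
                              sd_type = c("sample", "population")) {
  homogeneity_filter(zenith_filter(retrievals, max_zenith), sd_limit, sd_type)
}
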