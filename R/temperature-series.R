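#' Construct an irregular surface water temperature series
#'
#' One site/depth record of dated surface water temperatures (surface being
#' the 0--1 m layer for most monitored lakes). Observations are sorted by
#' date; temperatures outside a plausibility band trigger a warning only, as
#' extreme but genuine values do occur (ice-covered or hypersaline systems).
#'
#' @param dates observation dates (coerced with \code{as.Date}).
#' @param temp_c water temperatures, degrees Celsius; must be finite.
#' @param site_id identifier linking observations to lake metadata.
#' @param depth_label free-text depth descriptor, e.g. \code{"0-1 m"}.
#' @param plausible_range warn when temperatures fall outside this range
#'   (degrees C); set to \code{NULL} to disable the check.
#' @return A \code{temperature_series} object.
#' @export
temperature_series <- function(dates, temp_c, site_id = "site",
                               depth_label = "0-1 m",
                               plausible_range = c(-5, 45)) {
  dates <- as.Date(dates)
  temp_c <- as.numeric(temp_c)
  if (length(dates) != length(temp_c)) {
    stop("`dates` and `temp_c` must have the same length")
  }
  if (anyNA(dates)) stop("unparseable observation dates")
  if (length(temp_c) && any(!is.finite(temp_c))) {
    stop("temperatures must be finite")
  }
  if (!is.null(plausible_range) && length(temp_c)) {
    bad <- temp_c < plausible_range[1] | temp_c > plausible_range[2]
    if (any(bad)) {
      warning(sum(bad), " temperature(s) outside the plausible range [",
              plausible_range[1], ", ", plausible_range[2], "] degC")
    }
  }
  ord <- order(dates)
  structure(
    list(site_id = site_id, depth_label = depth_label,
         dates = dates[ord], temp_c = temp_c[ord]),
    class = "temperature_series"
  )
}

#' Collapse same-day replicate observations to their daily mean
#'
#' Multiple observations on one calendar date (profiles, sub-daily loggers)
#' are replaced by their arithmetic mean so that the series has at most one
#' value per day, the resolution at which interpolation operates.
#'
#' @param series a \code{temperature_series}.
#' @return A \code{temperature_series} with strictly increasing dates.
#' @export
dedupe_daily <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$dates) == 0 || !anyDuplicated(series$dates)) {
    return(series)
  }
  agg <- tapply(series$temp_c, as.numeric(series$dates), mean)
  temperature_series(
    dates = as.Date(as.numeric(names(agg)), origin = "1970-01-01"),
    temp_c = as.numeric(agg),
    site_id = series$site_id, depth_label = series$depth_label,
    plausible_range = NULL
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  n <- length(x$dates)
  cat(sprintf("<temperature_series '%s' (%s): %d obs", x$site_id,
              x$depth_label, n))
  if (n > 0) {
    cat(sprintf(", %s .. %s", format(min(x$dates)), format(max(x$dates))))
  }
  cat(">\n")
  invisible(x)
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(site_id = rep(x$site_id, length(x$dates)),
             date = x$dates, depth_label = rep(x$depth_label, length(x$dates)),
             temperature_c = x$temp_c, stringsAsFactors = FALSE)
}

# day-of-year (1..366) from the actual calendar
.doy <- function(dates) as.POSIXlt(dates)$yday + 1L
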