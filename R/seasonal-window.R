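#' @keywords internal
"_PACKAGE"

# month initials used to build/parse 3-letter window codes
.month_initials <- c("J", "F", "M", "A", "M", "J", "J", "A", "S", "O", "N", "D")

# all 12 consecutive-triple codes, named by starting month; all are distinct
.window_codes <- local({
  codes <- vapply(1:12, function(m) {
    paste0(.month_initials[((m - 1 + 0:2) %% 12) + 1], collapse = "")
  }, character(1))
  stats::setNames(1:12, codes)
})

.first_of_month <- function(year, month) {
  as.Date(sprintf("%04d-%02d-01", year, month))
}

new_seasonal_window <- function(start_month, year, label) {
  months <- ((start_month - 1 + 0:2) %% 12) + 1
  start_date <- .first_of_month(year, start_month)
  # end = last day of the third month (which may fall in the next calendar
  # year for windows that wrap, e.g. DJF)
  m4 <- start_month + 3
  end_year <- year + (m4 - 1) %/% 12
  end_date <- .first_of_month(end_year, ((m4 - 1) %% 12) + 1) - 1
  structure(
    list(months = months, year = year, start_date = start_date,
         end_date = end_date, label = label),
    class = "seasonal_window"
  )
}

#' Resolve the 3-month "summer" averaging window for a lake
#'
#' Lake-year means are harmonized over a fixed 3-month period chosen by
#' latitude: July--September (JAS) in the extratropical Northern Hemisphere
#' and January--March (JFM) in the extratropical Southern Hemisphere. Within
#' the tropics (|latitude| < 23.5 degrees) the assignment is flipped -- JAS
#' south of the equator and JFM north of it -- so that the window targets the
#' dry season and maximizes cloud-free satellite retrievals. A per-site
#' override code (e.g. \code{"JJA"} for high-arctic lakes whose September is
#' already frozen) takes precedence when supplied.
#'
#' Boundary conventions: latitude exactly 0 counts as northern tropical
#' (JFM); |latitude| exactly 23.5 counts as extratropical.
#'
#' @param latitude decimal degrees, in [-90, 90].
#' @param year calendar year the window belongs to.
#' @param override optional 3-letter month code (one of the 12 consecutive
#'   triples \code{"JFM"}, \code{"FMA"}, ..., \code{"DJF"}) that wins over
#'   the latitude rule.
#' @return A \code{seasonal_window} object: list with \code{months} (ordered
#'   month numbers), \code{year}, \code{start_date}, \code{end_date}
#'   (inclusive calendar dates) and \code{label}.
#' @examples
#' summer_window(46.4, 1998)   # Laurentian Great Lakes -> JAS
#' summer_window(-34.9, 2001)  # Adelaide reservoirs -> JFM
#' summer_window(-6.5, 2003)   # tropical southern -> JAS (dry season)
#' summer_window(68.6, 2000, override = "JJA")
#' @export
summer_window <- function(latitude, year, override = NULL) {
  stopifnot(length(latitude) == 1, length(year) == 1)
  if (!is.finite(latitude) || abs(latitude) > 90) {
    stop("`latitude` must be a finite value in [-90, 90], got ", latitude)
  }
  if (!is.null(override)) {
    m <- unname(.window_codes[toupper(override)])
    if (is.na(m)) {
      stop("unknown window code '", override, "'; valid codes: ",
           paste(names(.window_codes), collapse = ", "))
    }
    return(new_seasonal_window(m, year, toupper(override)))
  }
  label <- if (latitude >= 23.5) {
    "JAS"
  } else if (latitude <= -23.5) {
    "JFM"
  } else if (latitude < 0) {
    "JAS"   # tropical southern
  } else {
    "JFM"   # tropical northern, including the equator itself
  }
  new_seasonal_window(.window_codes[[label]], year, label)
}

#' The 3-month "winter" window opposite summer
#'
#' Winter is the 3-month block opposite summer in the calendar year: JFM for
#' JAS lakes and vice versa. For an override code the complement is the block
#' offset by six months, labeled by the calendar year of its first month
#' (e.g. summer JJA in year y pairs with DJF starting 1 December of y).
#'
#' @inheritParams summer_window
#' @return A \code{seasonal_window}.
#' @export
winter_window <- function(latitude, year, override = NULL) {
  s <- summer_window(latitude, year, override)
  m <- ((s$months[1] + 5) %% 12) + 1
  label <- names(.window_codes)[match(m, .window_codes)]
  new_seasonal_window(m, year, label)
}

#' Daily date grid of a seasonal window
#'
#' Every calendar day from the window start to its end, inclusive. A JAS
#' window always has 92 days; JFM has 90 (91 in leap years).
#'
#' @param window a \code{seasonal_window}.
#' @return Vector of \code{Date}s.
#' @export
daily_grid <- function(window) {
  stopifnot(inherits(window, "seasonal_window"))
  seq(window$start_date, window$end_date, by = "day")
}

#' @export
print.seasonal_window <- function(x, ...) {
  cat(sprintf("<seasonal_window %s %d: %s .. %s (%d days)>\n",
              x$label, x$year, format(x$start_date), format(x$end_date),
              as.integer(x$end_date - x$start_date) + 1L))
  invisible(x)
}
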