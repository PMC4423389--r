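#' Controlled vocabulary of the values table
#'
#' The variable labels allowed in the long-format values file: harmonized
#' summer lake temperatures from both platforms, NCEP and CRU air
#' temperature summaries, SRB shortwave/longwave/total radiation, and
#' PATMOS cloud cover, each for summer, winter and/or annual periods.
#'
#' @format Character vector of variable labels.
#' @export
gltc_variables <- c(
  "Lake_Temp_Summer_InSitu", "Lake_Temp_Summer_Satellite",
  "Air_Temp_Mean_Summer_NCEP", "Air_Temp_Mean_Annual_NCEP",
  "Air_Temp_Mean_Winter_NCEP",
  "Radiation_Shortwave_Summer", "Radiation_Shortwave_Winter",
  "Radiation_Shortwave_Annual",
  "Radiation_Longwave_Summer", "Radiation_Longwave_Winter",
  "Radiation_Longwave_Annual",
  "Radiation_Total_Summer", "Radiation_Total_Winter",
  "Radiation_Total_Annual",
  "Cloud_Cover_Summer", "Cloud_Cover_Winter", "Cloud_Cover_Annual",
  "Air_Temp_Max_Summer_CRU", "Air_Temp_Max_Annual_CRU",
  "Air_Temp_Max_Winter_CRU",
  "Air_Temp_Mean_Summer_CRU", "Air_Temp_Mean_Annual_CRU",
  "Air_Temp_Mean_Winter_CRU",
  "Air_Temp_Min_Summer_CRU", "Air_Temp_Min_Annual_CRU",
  "Air_Temp_Min_Winter_CRU",
  "Air_Temp_DTR_Summer_CRU", "Air_Temp_DTR_Annual_CRU",
  "Air_Temp_DTR_Winter_CRU"
)

.lake_required_cols <- c("siteID", "Lake_name", "lake_or_reservoir",
                         "location", "region", "latitude", "longitude",
                         "elevation", "source", "sampling_depth",
                         "sampling_time_of_day", "time_period", "contributor")
.lake_numeric_cols <- c("latitude", "longitude", "geospatial_accuracy_km",
                        "elevation", "mean_depth_m", "max_depth_m",
                        "surface_area_km2", "volume_km3")
.lake_optional_cols <- c("Other_names", "geospatial_accuracy_km",
                         "mean_depth_m", "max_depth_m", "surface_area_km2",
                         "volume_km3")

# "", "NA", "NaN" (any case) are accepted missing-value spellings on read
.parse_numeric <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA", "NaN", "na", "nan")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read the lake metadata table
#'
#' Reads the comma-delimited lake information file (one row per site:
#' identity, location, geomorphometry, sampling protocol and contributor).
#' Empty cells become missing values, never zeros. Missing required columns
#' raise a schema error naming the column; unparseable or out-of-range
#' coordinates raise a row-level error carrying the file line number.
#'
#' @param path path to the CSV file (header row with the standard labels; a
#'   space in \code{"geospatial accuracy_km"} is normalized to an
#'   underscore).
#' @return Data frame of lake records, one row per site.
#' @export
read_lake_information <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  names(raw) <- gsub(" ", "_", names(raw))
  missing_cols <- setdiff(.lake_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("lake information file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(.lake_numeric_cols, names(raw))) {
    parsed <- .parse_numeric(raw[[col]])
    bad <- is.na(parsed) & !(trimws(raw[[col]]) %in% c("", "NA", "NaN", "na", "nan"))
    if (any(bad) && col %in% c("latitude", "longitude")) {
      stop("unparseable ", col, " at file line(s) ",
           paste(which(bad) + 1, collapse = ", "))
    }
    raw[[col]] <- parsed
  }
  for (col in setdiff(names(raw), .lake_numeric_cols)) {
    raw[[col]][trimws(raw[[col]]) %in% c("", "NA")] <- NA
  }
  bad_lat <- !is.na(raw$latitude) & abs(raw$latitude) > 90
  bad_lon <- !is.na(raw$longitude) & abs(raw$longitude) > 180
  if (any(bad_lat | bad_lon)) {
    stop("coordinate out of bounds at file line(s) ",
         paste(which(bad_lat | bad_lon) + 1, collapse = ", "))
  }
  both <- !is.na(raw$mean_depth_m) & !is.na(raw$max_depth_m)
  if (any(both) && any(raw$mean_depth_m[both] > raw$max_depth_m[both])) {
    warning("mean_depth_m exceeds max_depth_m for site(s): ",
            paste(raw$siteID[both][raw$mean_depth_m[both] >
                                     raw$max_depth_m[both]], collapse = ", "))
  }
  bad_code <- !is.na(raw$time_period) &
    !(raw$time_period %in% names(.window_codes))
  if (any(bad_code)) {
    warning("unrecognized time_period code(s): ",
            paste(unique(raw$time_period[bad_code]), collapse = ", "))
  }
  raw
}

#' Write the lake metadata table
#'
#' Inverse of [read_lake_information()]: UTF-8, comma-delimited, missing
#' cells written as empty strings. Reading the written file recovers the
#' records.
#'
#' @param lakes data frame of lake records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lake_information <- function(lakes, path) {
  utils::write.csv(lakes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the long-format values table
#'
#' Reads the comma-delimited values file: one record per (site, year,
#' variable), with variables drawn from the controlled vocabulary
#' ([gltc_variables]). Records with labels outside the vocabulary are
#' quarantined with a warning (or raise an error in strict mode) and
#' returned in the \code{"quarantined"} attribute. Duplicate (site, year,
#' variable) keys are an error.
#'
#' @param path path to the CSV file (columns \code{siteID}, \code{year},
#'   \code{variable}, \code{value}).
#' @param strict error instead of quarantining unknown variable labels.
#' @return Data frame of value records; empty \code{value} cells are
#'   \code{NA}.
#' @export
read_values <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(c("siteID", "year", "variable", "value"), names(raw))
  if (length(missing_cols)) {
    stop("values file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$year <- as.integer(.parse_numeric(raw$year))
  raw$value <- .parse_numeric(raw$value)
  key <- paste(raw$siteID, raw$year, raw$variable)
  if (anyDuplicated(key)) {
    stop("duplicate (siteID, year, variable) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  unknown <- !(raw$variable %in% gltc_variables)
  quarantined <- NULL
  if (any(unknown)) {
    msg <- paste0("variable label(s) outside the controlled vocabulary: ",
                  paste(unique(raw$variable[unknown]), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; records quarantined")
    quarantined <- raw[unknown, , drop = FALSE]
    raw <- raw[!unknown, , drop = FALSE]
  }
  attr(raw, "quarantined") <- quarantined
  raw
}

#' Write the long-format values table
#'
#' @param values data frame of value records (\code{siteID}, \code{year},
#'   \code{variable}, \code{value}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_values <- function(values, path) {
  utils::write.csv(values[, c("siteID", "year", "variable", "value")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Pivot the long values table to one column per variable
#'
#' Convenience exporter: rows keyed by (siteID, year), one column per
#' variable label. Absent records become \code{NA}.
#'
#' @param values long-format values data frame.
#' @return Wide data frame.
#' @export
values_to_wide <- function(values) {
  keys <- unique(values[, c("siteID", "year")])
  keys <- keys[order(keys$siteID, keys$year), , drop = FALSE]
  rownames(keys) <- NULL
  vars <- intersect(gltc_variables, unique(values$variable))
  kid <- paste(keys$siteID, keys$year)
  for (v in vars) {
    sub <- values[values$variable == v, ]
    keys[[v]] <- sub$value[match(kid, paste(sub$siteID, sub$year))]
  }
  keys
}

#' Write per-site extrapolation processing logs
#'
#' Writes one human-readable text file per site describing every
#' extrapolated lake-year: which boundary was extended, the shifted
#' parabolic equation \code{temperature = a*DoY^2 + b*DoY + c} with its
#' fitted coefficients, the period the extrapolation covered, and the
#' pooled fit's R-squared. Years listed in \code{years} with no entries are
#' reported as having needed no extrapolation.
#'
#' @param entries data frame of log entries as attached to
#'   \code{seasonal_mean} objects (\code{site_id}, \code{year}, \code{side},
#'   \code{a}, \code{b}, \code{c}, \code{r_squared}, \code{period_start},
#'   \code{period_end}); may be \code{NULL} or empty.
#' @param dir output directory (created if needed).
#' @param years optional integer years to report explicitly even when no
#'   extrapolation was performed.
#' @param site_ids sites to write files for; defaults to the sites present
#'   in \code{entries}.
#' @return Paths of the written files, invisibly.
#' @export
write_processing_log <- function(entries, dir, years = NULL,
                                 site_ids = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(site_ids)) {
    site_ids <- if (is.null(entries) || nrow(entries) == 0) character(0) else
      unique(entries$site_id)
  }
  num <- function(x) sprintf("%.10g", x)
  paths <- character(0)
  for (site in site_ids) {
    e <- if (is.null(entries)) NULL else
      entries[entries$site_id == site, , drop = FALSE]
    all_years <- sort(unique(c(years, if (!is.null(e)) e$year)))
    lines <- c(paste0("Processing log for site ", site),
               strrep("=", nchar(site) + 24), "")
    for (y in all_years) {
      lines <- c(lines, paste0("Year ", y, ":"))
      ey <- if (is.null(e)) NULL else e[e$year == y, , drop = FALSE]
      if (is.null(ey) || nrow(ey) == 0) {
        lines <- c(lines, "  no extrapolation performed", "")
        next
      }
      for (i in seq_len(nrow(ey))) {
        side_txt <- if (ey$side[i] == "start") "beginning period" else
          "end period"
        lines <- c(lines,
          paste0("  extrapolation used for the ", side_txt),
          paste0("  equation: temperature = ", num(ey$a[i]), "*DoY^2 + ",
                 num(ey$b[i]), "*DoY + ", num(ey$c[i])),
          paste0("  period covered: ", format(ey$period_start[i]), " to ",
                 format(ey$period_end[i])),
          paste0("  R^2 of pooled fit: ", num(ey$r_squared[i])))
      }
      lines <- c(lines, "")
    }
    p <- file.path(dir, paste0(site, "_processing_log.txt"))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
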