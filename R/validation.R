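#' Root-mean-square error between two paired series
#'
#' RMSE over the years where both series carry a value; \code{NA} when there
#' is no overlap.
#'
#' @param values_a,values_b numeric vectors of equal length (paired by
#'   position, typically by year); \code{NA} marks missing lake-years.
#' @return RMSE, same units as the inputs.
#' @export
paired_rmse <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  ok <- !is.na(values_a) & !is.na(values_b)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((values_a[ok] - values_b[ok])^2))
}

#' Interannual anomalies about a baseline-period mean
#'
#' Each year's value minus the lake's mean over the available baseline
#' years. Anomalies remove constant offsets between measurement platforms
#' (e.g. residual skin-bulk or timing biases), so platform comparisons on
#' anomalies isolate interannual agreement.
#'
#' @param values seasonal means per year (\code{NA} = missing).
#' @param years calendar years aligned with \code{values}.
#' @param baseline two-element year range over which the reference mean is
#'   taken; only years with values contribute.
#' @return Anomaly vector aligned with \code{values}.
#' @export
anomalies <- function(values, years, baseline = c(1985, 2009)) {
  stopifnot(length(values) == length(years), length(baseline) == 2)
  in_base <- years >= baseline[1] & years <= baseline[2] & !is.na(values)
  if (!any(in_base)) return(rep(NA_real_, length(values)))
  values - mean(values[in_base])
}

#' Linear warming/cooling trend of a seasonal-mean series
#'
#' Slope of seasonal mean on calendar year. Ordinary least squares is the
#' default; a Theil-Sen (median of pairwise slopes) option is available for
#' outlier-heavy series.
#'
#' @inheritParams anomalies
#' @param min_years minimum number of non-missing years required.
#' @param estimator \code{"ols"} (default) or \code{"theil_sen"}.
#' @return Trend in degC per year, or \code{NA} below the year floor.
#' @export
lake_trend <- function(values, years, min_years = 3,
                       estimator = c("ols", "theil_sen")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(values)
  if (sum(ok) < min_years || length(unique(years[ok])) < 2) return(NA_real_)
  y <- values[ok]; x <- years[ok]
  if (estimator == "ols") {
    unname(stats::coef(stats::lm(y ~ x))[2])
  } else {
    ij <- utils::combn(length(x), 2)
    dx <- x[ij[2, ]] - x[ij[1, ]]
    stats::median(((y[ij[2, ]] - y[ij[1, ]]) / dx)[dx != 0])
  }
}

#' Cross-platform validation of satellite against in situ seasonal means
#'
#' For lakes observed by both platforms, compares the two seasonal-mean
#' series three ways over their temporally matched years (years where both
#' platforms report): RMSE of the means themselves (pooling all year-pairs
#' across lakes), RMSE after transforming each matched series to anomalies
#' about its baseline-period mean (removing constant per-lake platform
#' offsets), and RMSE of the differences between per-lake linear trends.
#' Constant per-lake offsets inflate only the first statistic -- anomaly and
#' trend RMSEs are invariant to them.
#'
#' @param pairs data frame with columns \code{site_id}, \code{year},
#'   \code{insitu}, \code{satellite} (degC seasonal means, \code{NA} =
#'   missing).
#' @param baseline year range for the anomaly reference mean.
#' @param min_trend_years per-lake floor of matched years for a trend.
#' @return A \code{validation_result} list: \code{rmse_means},
#'   \code{rmse_anomalies} (degC), \code{rmse_trends} (degC/yr),
#'   \code{n_lakes}, \code{n_pairs}, and a \code{per_lake} breakdown.
#' @export
cross_platform_validation <- function(pairs, baseline = c(1985, 2009),
                                      min_trend_years = 3) {
  stopifnot(all(c("site_id", "year", "insitu", "satellite") %in% names(pairs)))
  m <- pairs[!is.na(pairs$insitu) & !is.na(pairs$satellite), , drop = FALSE]
  if (nrow(m) == 0) {
    return(structure(list(rmse_means = NA_real_, rmse_anomalies = NA_real_,
                          rmse_trends = NA_real_, n_lakes = 0L, n_pairs = 0L,
                          per_lake = NULL), class = "validation_result"))
  }
  per_lake <- lapply(split(m, m$site_id), function(d) {
    a_i <- anomalies(d$insitu, d$year, baseline)
    a_s <- anomalies(d$satellite, d$year, baseline)
    data.frame(
      site_id = d$site_id[1], n_pairs = nrow(d),
      rmse_means = paired_rmse(d$insitu, d$satellite),
      rmse_anomalies = paired_rmse(a_i, a_s),
      trend_insitu = lake_trend(d$insitu, d$year, min_trend_years),
      trend_satellite = lake_trend(d$satellite, d$year, min_trend_years),
      stringsAsFactors = FALSE)
  })
  per_lake <- do.call(rbind, unname(per_lake))
  anom_all <- do.call(rbind, lapply(split(m, m$site_id), function(d) {
    data.frame(a = anomalies(d$insitu, d$year, baseline),
               b = anomalies(d$satellite, d$year, baseline))
  }))
  trend_diff <- per_lake$trend_satellite - per_lake$trend_insitu
  trend_diff <- trend_diff[!is.na(trend_diff)]
  structure(
    list(rmse_means = paired_rmse(m$insitu, m$satellite),
         rmse_anomalies = paired_rmse(anom_all$a, anom_all$b),
         rmse_trends = if (length(trend_diff))
           sqrt(mean(trend_diff^2)) else NA_real_,
         n_lakes = length(unique(m$site_id)), n_pairs = nrow(m),
         per_lake = per_lake),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>\n")
  cat(sprintf("  lakes: %d, matched year-pairs: %d\n", x$n_lakes, x$n_pairs))
  cat(sprintf("  RMSE of means:     %s degC\n", format(x$rmse_means)))
  cat(sprintf("  RMSE of anomalies: %s degC\n", format(x$rmse_anomalies)))
  cat(sprintf("  RMSE of trends:    %s degC/yr\n", format(x$rmse_trends)))
  invisible(x)
}
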